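test_that("Gram centering matches the hand-computed double-centering and its identities", {
  # constant matrix centers to zero
  expect_equal(unname(center_kernel(matrix(1, 3, 3))), matrix(0, 3, 3),
               ignore_attr = TRUE)
  # hand computation of H K H with H = I - (1/2) 11'
  K <- matrix(c(1, 0.5, 0.5, 1), 2)
  Kc <- center_kernel(K)
  expect_equal(unname(Kc), matrix(c(0.25, -0.25, -0.25, 0.25), 2),
               ignore_attr = TRUE)
  # rows of any centered Gram matrix sum to zero; centering is idempotent
  K2 <- kernel_matrix(rand_X(12, 5, seed = 4), rbf_kernel(0.2))
  Kc2 <- center_kernel(K2)
  expect_lt(max(abs(rowSums(Kc2))), 1e-10 * nrow(K2))
  expect_equal(center_kernel(Kc2), Kc2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(center_kernel(matrix(1:9, 3)), "symmetric")
})

test_that("the 2x2 eigenproblem reproduces the hand solution and +/-0.5 training scores", {
  Kc <- center_kernel(matrix(c(1, 0.5, 0.5, 1), 2))
  eg <- kpca_eigen(Kc, q = 1)
  expect_equal(eg$eigenvalues, 0.5)
  expect_equal(drop(eg$dual_coefs), c(1, -1))          # a' Kc a = 1
  expect_equal(drop(crossprod(eg$dual_coefs, Kc %*% eg$dual_coefs)), 1)
  scores <- unname(Kc) %*% eg$dual_coefs
  expect_equal(drop(scores), c(0.5, -0.5))
})

test_that("dual coefficients are Gram-orthonormal and rank deficiency is handled", {
  X <- rand_X(15, 6, seed = 5)
  m <- kpca_fit(X, rbf_kernel(0.1), q = 6, scale = FALSE)
  Kc <- center_kernel(m$K)
  G <- crossprod(m$dual_coefs, unname(Kc) %*% m$dual_coefs)
  expect_equal(unname(G), diag(m$q), tolerance = 1e-8)

  # duplicated identical samples: centered Gram matrix rank collapses, q is
  # reduced with a warning; all-identical samples are degenerate
  Xdup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  expect_warning(mdup <- kpca_fit(Xdup, rbf_kernel(0.5), q = 3, scale = FALSE),
                 "rank")
  expect_equal(mdup$q, 1)
  Kc0 <- center_kernel(kernel_matrix(rbind(c(1, 1), c(1, 1)), rbf_kernel(1)))
  expect_error(kpca_eigen(Kc0, 1), "degenerate")
})

test_that("projecting the training data reproduces the stored scores", {
  X <- rand_X(10, 4, seed = 6)
  for (scale in c(TRUE, FALSE)) {
    m <- suppressWarnings(kpca_fit(X, rbf_kernel(0.3), q = 3, scale = scale))
    expect_equal(unname(kpca_project(m, X)), unname(m$scores), tolerance = 1e-10)
  }
  m <- kpca_fit(X, rbf_kernel(0.3), q = 2, scale = FALSE)
  expect_error(kpca_project(m, X[, 1:3]), "mismatch")
  # symmetric 2-point configuration: a point equidistant from both training
  # samples projects to the origin
  m2 <- kpca_fit(rbind(c(0, 0), c(1, 1)), rbf_kernel(0.5), q = 1, scale = FALSE)
  expect_equal(unname(drop(kpca_project(m2, rbind(c(1, 0))))), 0,
               tolerance = 1e-12)
})

test_that("linear-kernel KPCA equals classical covariance PCA (scores and variance fractions)", {
  X <- rand_X(30, 8, seed = 7)
  m <- kpca_fit(X, linear_kernel(), q = 5, scale = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  for (k in 1:5) {
    d <- min(max(abs(m$scores[, k] - pc$x[, k])),
             max(abs(m$scores[, k] + pc$x[, k])))
    expect_lt(d, 1e-8)
  }
  expect_equal(explained_variance(m),
               (pc$sdev^2 / sum(pc$sdev^2))[1:5], tolerance = 1e-10)
})

test_that("explained variance uses the full spectrum and the n-normalized eigenvalues are exposed", {
  m <- structure(list(eigenvalues = 3, eigenvalues_all = c(3, 1, -1e-16),
                      X = matrix(0, 4, 2)), class = "kpca_model")
  expect_equal(explained_variance(m), 0.75)
  expect_equal(kpca_eigenvalues(m), 3)
  expect_equal(kpca_eigenvalues(m, normalized = TRUE), 3 / 4)
  m1 <- structure(list(eigenvalues = 2, eigenvalues_all = c(2, 0)),
                  class = "kpca_model")
  expect_equal(explained_variance(m1), 1)
})

test_that("scores are invariant to training-sample permutation", {
  X <- rand_X(14, 5, seed = 8)
  perm <- sample(14)
  m <- kpca_fit(X, rbf_kernel(0.2), q = 3, scale = TRUE)
  mp <- kpca_fit(X[perm, ], rbf_kernel(0.2), q = 3, scale = TRUE)
  expect_equal(unname(mp$scores), unname(m$scores[perm, ]), tolerance = 1e-8)
})

test_that("sigma selection maximizes first-q explained variance over the grid", {
  d <- make_clustered_data(n = 30, p = 20, n_informative = 5, n_clusters = 2,
                           separation = 5, seed = 3)
  grid <- c(1e-7, 1e-5, 1e-3)
  s <- select_sigma(d$X, grid = grid, q = 2)
  tab <- attr(s, "table")
  # brute-force re-evaluation of the objective
  obj <- vapply(grid, function(sg) {
    m <- kpca_fit(d$X, rbf_kernel(sg), q = 2)
    sum(explained_variance(m))
  }, numeric(1))
  expect_equal(tab$cum_explained_variance, obj, tolerance = 1e-10)
  expect_equal(as.numeric(s), grid[which.max(obj)])
  expect_equal(as.numeric(select_sigma(d$X, grid = 0.37, q = 2)), 0.37)
  # n = 2: every bandwidth gives one positive eigenvalue, a full tie, so the
  # smaller sigma wins
  s2 <- select_sigma(rbind(c(0, 1), c(1, 0)), grid = c(0.2, 0.1), q = 1)
  expect_equal(as.numeric(s2), 0.1)
  expect_error(select_sigma(d$X, grid = numeric(0)), "nonempty")
})

test_that("scores agree with an independent kernel PCA implementation", {
  skip_if_not_installed("kernlab")
  X <- rand_X(20, 6, seed = 9)
  sig <- 0.15
  m <- kpca_fit(X, rbf_kernel(sig), q = 4, scale = FALSE)
  ref <- kernlab::kpca(X, kernel = "rbfdot", kpar = list(sigma = sig),
                       features = 4)
  # kernlab solves eigen(Kc/n) and normalizes its dual coefficients against
  # those eigenvalues, so its scores are ours times sqrt(n) and its
  # eigenvalues ours divided by n
  expect_equal(kernlab::eig(ref), kpca_eigenvalues(m, normalized = TRUE),
               ignore_attr = TRUE, tolerance = 1e-8)
  rot <- kernlab::rotated(ref)
  for (k in 1:4) {
    d <- min(max(abs(sqrt(20) * m$scores[, k] - rot[, k])),
             max(abs(sqrt(20) * m$scores[, k] + rot[, k])))
    expect_lt(d, 1e-6)
  }
})
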