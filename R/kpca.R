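#' Double-center a Gram matrix
#'
#' Applies the feature-space centering
#' \deqn{\tilde K = K - \tfrac{1}{n} K 1 1^T - \tfrac{1}{n} 1 1^T K
#'       + \tfrac{1}{n^2} (1^T K 1) 1 1^T,}
#' which makes the implicit mapped points zero-mean in feature space. The
#' column means and grand mean of `K` are attached as attributes
#' (`"col_means"`, `"grand_mean"`) so that out-of-sample projection can reuse
#' them without rebuilding `K`.
#'
#' @param K symmetric kernel matrix.
#' @param tol symmetry tolerance (relative to `max(abs(K))`).
#' @return The centered matrix, rows and columns summing to zero.
#' @export
center_kernel <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > tol * max(abs(K), 1))
    stop("'K' must be a symmetric kernel matrix", call. = FALSE)
  cm <- colMeans(K)
  gm <- mean(cm)
  Kc <- K - outer(rep(1, nrow(K)), cm) - outer(cm, rep(1, nrow(K))) + gm
  Kc <- (Kc + t(Kc)) / 2
  attr(Kc, "col_means") <- cm
  attr(Kc, "grand_mean") <- gm
  Kc
}

#' Eigendecomposition of a centered Gram matrix
#'
#' Solves the kernel PCA eigenproblem on a centered Gram matrix and returns
#' the dual coefficients normalized so that each principal axis
#' \eqn{\tilde v^k = \sum_i \tilde a_i^k \phi(x_i)} has unit norm in feature
#' space, i.e. \eqn{\tilde a^{kT} \tilde K \tilde a^k = 1}
#' (`dual_coefs` column k is the k-th eigenvector divided by the square root
#' of its eigenvalue). Eigenvalues below `eig_tol * max(eigenvalue)` are
#' treated as numerically zero rank and dropped; if `q` exceeds the retained
#' rank it is reduced with a warning. Each dual-coefficient column is flipped
#' so its largest-magnitude entry is positive, giving a deterministic sign.
#'
#' @param Kc centered Gram matrix (see [center_kernel()]).
#' @param q number of components to retain.
#' @param eig_tol relative eigenvalue cutoff for rank detection.
#' @return A list with `eigenvalues` (the retained eigenvalues of the centered
#'   Gram matrix, descending), `eigenvalues_all` (the full spectrum),
#'   `dual_coefs` (n x q) and the effective `q`.
#' @export
kpca_eigen <- function(Kc, q, eig_tol = 1e-12) {
  if (q < 1) stop("'q' must be >= 1", call. = FALSE)
  eg <- eigen(Kc, symmetric = TRUE)
  vals <- eg$values
  if (max(vals) <= 0)
    stop("degenerate kernel matrix: no positive eigenvalue", call. = FALSE)
  keep <- vals > eig_tol * max(vals)
  rank <- sum(keep)
  if (q > rank) {
    warning(sprintf("q = %d exceeds the numerical rank %d of the centered kernel matrix; using q = %d",
                    q, rank, rank), call. = FALSE)
    q <- rank
  }
  lambda <- vals[seq_len(q)]
  A <- eg$vectors[, seq_len(q), drop = FALSE]
  A <- sweep(A, 2, sqrt(lambda), "/")
  # deterministic sign: largest-magnitude entry of each column positive
  for (k in seq_len(q)) {
    i <- which.max(abs(A[, k]))
    if (A[i, k] < 0) A[, k] <- -A[, k]
  }
  list(eigenvalues = lambda, eigenvalues_all = vals, dual_coefs = A, q = q)
}

#' Fit kernel PCA
#'
#' Builds the Gram matrix of `X` under `kernel`, centers it in feature space,
#' and extracts the leading `q` kernel principal axes. By default each feature
#' is z-scored (mean 0, sd 1) before the kernel is applied; zero-variance
#' features are centered to 0 and left unscaled, with a warning.
#'
#' @param X numeric sample-by-feature matrix (rows are samples). Row and
#'   column names, when present, are carried through to scores and rankings.
#' @param kernel a [rbf_kernel()] or [linear_kernel()] spec.
#' @param q number of kernel principal components to retain.
#' @param scale logical; z-score features before the kernel (default `TRUE`).
#' @param eig_tol relative eigenvalue cutoff, see [kpca_eigen()].
#' @return An object of class `kpca_model` with elements `scores` (n x q
#'   training coordinates), `eigenvalues` (of the centered Gram matrix),
#'   `eigenvalues_all`, `dual_coefs`, `q`, `kernel`, `X` (the preprocessed
#'   training matrix the kernel saw), `K`, `col_means_K`, `grand_mean_K`, and
#'   the preprocessing statistics `center`/`scaling`.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' m <- kpca_fit(X, rbf_kernel(0.5), q = 2)
#' head(m$scores)
#' explained_variance(m)
#' @export
kpca_fit <- function(X, kernel = rbf_kernel(1e-3), q = 2, scale = TRUE,
                     eig_tol = 1e-12) {
  stopifnot_kernel_spec(kernel)
  X <- as_data_matrix(X)
  pp <- preprocess_features(X, scale = scale)
  K <- kernel_matrix(pp$X, kernel)
  Kc <- center_kernel(K)
  eg <- kpca_eigen(Kc, q = q, eig_tol = eig_tol)
  scores <- unname(Kc) %*% eg$dual_coefs
  dimnames(scores) <- list(rownames(X), paste0("KPC", seq_len(eg$q)))
  structure(list(
    scores          = scores,
    eigenvalues     = eg$eigenvalues,
    eigenvalues_all = eg$eigenvalues_all,
    dual_coefs      = eg$dual_coefs,
    q               = eg$q,
    kernel          = kernel,
    X               = pp$X,
    center          = pp$center,
    scaling         = pp$scaling,
    scaled          = scale,
    K               = K,
    col_means_K     = attr(Kc, "col_means"),
    grand_mean_K    = attr(Kc, "grand_mean"),
    feature_ids     = colnames(X),
    sample_ids      = rownames(X)
  ), class = "kpca_model")
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("Kernel PCA model: %d samples, %d features, q = %d\n",
              nrow(x$X), ncol(x$X), x$q))
  print(x$kernel)
  ev <- explained_variance(x)
  cat("Explained variance:", paste(sprintf("%.1f%%", 100 * ev), collapse = ", "),
      sprintf("(cumulative %.1f%%)\n", 100 * sum(ev)))
  invisible(x)
}

as_data_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("'X' must be a numeric matrix", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X)))
    stop("duplicate feature names in 'X'", call. = FALSE)
  X
}

preprocess_features <- function(X, scale = TRUE) {
  if (!scale)
    return(list(X = X, center = NULL, scaling = NULL))
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s) centered but not scaled", sum(zero)),
            call. = FALSE)
    sds[zero] <- 1
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  list(X = Xs, center = ctr, scaling = sds)
}

apply_preprocess <- function(model, X_new) {
  if (!model$scaled) return(X_new)
  sweep(sweep(X_new, 2, model$center), 2, model$scaling, "/")
}

#' Project new samples onto the kernel principal axes
#'
#' Out-of-sample projection: for a new point \eqn{x} with kernel row
#' \eqn{Z = (k(x, x_i))_i}, the coordinates are
#' \eqn{(Z^T - \tfrac1n 1^T K)(I - \tfrac1n 1 1^T)\,\tilde a}. Projecting the
#' training data reproduces the stored training scores.
#'
#' @param model a fitted [kpca_fit()] model.
#' @param X_new matrix of new samples; its columns must match the training
#'   features (by name when both are named).
#' @return An `m x q` score matrix.
#' @export
kpca_project <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$X)) {
    if (!is.null(colnames(X_new)) && !is.null(model$feature_ids) &&
        all(model$feature_ids %in% colnames(X_new))) {
      X_new <- X_new[, model$feature_ids, drop = FALSE]
    } else {
      missing <- setdiff(model$feature_ids, colnames(X_new))
      stop(sprintf("feature mismatch: model has %d features, new data %d%s",
                   ncol(model$X), ncol(X_new),
                   if (length(missing)) paste0(" (missing: ",
                     paste(utils::head(missing, 5), collapse = ", "), ")") else ""),
           call. = FALSE)
    }
  } else if (!is.null(colnames(X_new)) && !is.null(model$feature_ids) &&
             !identical(colnames(X_new), model$feature_ids) &&
             all(model$feature_ids %in% colnames(X_new))) {
    X_new <- X_new[, model$feature_ids, drop = FALSE]
  }
  Xp <- apply_preprocess(model, X_new)
  Z <- kernel_matrix(model$X, model$kernel, Y = Xp)  # m x n
  Zc <- Z - rowMeans(Z) -
    outer(rep(1, nrow(Z)), model$col_means_K) + model$grand_mean_K
  scores <- Zc %*% model$dual_coefs
  dimnames(scores) <- list(rownames(X_new), paste0("KPC", seq_len(model$q)))
  scores
}

#' Explained-variance fractions of a kernel PCA model
#'
#' The fraction of feature-space variance captured by each retained component:
#' the component's eigenvalue divided by the sum of *all* nonnegative
#' eigenvalues of the centered Gram matrix (not only the retained ones).
#'
#' @param model a fitted `kpca_model`.
#' @return Length-`q` numeric vector of fractions in `[0, 1]`.
#' @export
explained_variance <- function(model) {
  total <- sum(pmax(model$eigenvalues_all, 0))
  model$eigenvalues / total
}

#' Eigenvalues of a kernel PCA model
#'
#' By default the eigenvalues of the centered Gram matrix are returned (what
#' the solver produces). With `normalized = TRUE` they are divided by the
#' number of samples, the scale on which the feature-space covariance
#' eigenvalue problem is usually written.
#'
#' @param model a fitted `kpca_model`.
#' @param normalized divide by `n`?
#' @export
kpca_eigenvalues <- function(model, normalized = FALSE) {
  if (normalized) model$eigenvalues / nrow(model$X) else model$eigenvalues
}

#' Default bandwidth grid for the RBF kernel
#'
#' Thirteen log-spaced values from `1e-8` to `1e-2`, a range that brackets the
#' bandwidths appropriate for z-scored expression matrices from tens to tens of
#' thousands of features (the squared distances the kernel sees grow linearly
#' with the feature count).
#'
#' @export
default_sigma_grid <- function() 10^seq(-8, -2, length.out = 13)

#' Choose the RBF bandwidth by maximizing explained variance
#'
#' Evaluates every candidate bandwidth on a grid and returns the one whose
#' first `q` kernel principal components capture the largest cumulative
#' explained variance; ties are broken in favour of the smaller bandwidth.
#' The full (sigma, cumulative variance) table is attached as attribute
#' `"table"`.
#'
#' @param X sample-by-feature matrix.
#' @param grid positive candidate bandwidths.
#' @param q number of leading components the objective sums over.
#' @param scale z-score features first (as in [kpca_fit()]).
#' @return The selected bandwidth (numeric scalar) with the search table as an
#'   attribute.
#' @export
select_sigma <- function(X, grid = default_sigma_grid(), q = 2, scale = TRUE) {
  if (length(grid) < 1) stop("'grid' must be a nonempty vector", call. = FALSE)
  if (any(grid <= 0)) stop("'grid' values must be positive", call. = FALSE)
  X <- as_data_matrix(X)
  Xp <- suppressWarnings(preprocess_features(X, scale = scale))$X
  obj <- vapply(grid, function(s) {
    K <- kernel_matrix(Xp, rbf_kernel(s))
    vals <- eigen(center_kernel(K), symmetric = TRUE, only.values = TRUE)$values
    pos <- pmax(vals, 0)
    tot <- sum(pos)
    if (tot <= 0) return(0)
    sum(pos[seq_len(min(q, length(pos)))]) / tot
  }, numeric(1))
  ord <- order(-obj, grid)
  best <- ord[1]
  structure(grid[best],
            table = data.frame(sigma = grid, cum_explained_variance = obj))
}
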