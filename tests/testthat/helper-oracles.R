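# Independent oracles used across the suite. These deliberately avoid the
# vectorized code paths they check.

rand_X <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  dimnames(X) <- list(paste0("s", seq_len(n)), paste0("g", seq_len(p)))
  X
}

# central finite differences of the out-of-sample projection map along
# coordinate j, evaluated at every training point
fd_projection_field <- function(model, j, h = 1e-5) {
  n <- nrow(model$X)
  out <- matrix(0, n, model$q)
  for (a in seq_len(n)) {
    xp <- model$X[a, , drop = FALSE]
    xm <- xp
    xp[1, j] <- xp[1, j] + h
    xm[1, j] <- xm[1, j] - h
    out[a, ] <- (kpca_project(model, xp) - kpca_project(model, xm)) / (2 * h)
  }
  out
}

# per-feature ranking scores via a point-by-point loop over kernel_derivative
naive_ranking_scores <- function(model) {
  X <- model$X
  n <- nrow(X)
  B <- sweep(model$dual_coefs, 2, colMeans(model$dual_coefs))
  vapply(seq_len(ncol(X)), function(j) {
    norms <- vapply(seq_len(n), function(a) {
      dz <- vapply(seq_len(n), function(i)
        kernel_derivative(model$kernel, X[a, ], X[i, ], j), numeric(1))
      sqrt(sum((drop(dz %*% B))^2))
    }, numeric(1))
    mean(norms)
  }, numeric(1))
}

# NMI by direct entropy arithmetic on a contingency table
nmi_from_table <- function(tab, variant = "geometric") {
  n <- sum(tab)
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  pj <- tab / n
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (pj[i, j] > 0) mi <- mi + pj[i, j] * log(pj[i, j] / (pr[i] * pc[j]))
  denom <- if (variant == "geometric") sqrt(H(pr) * H(pc)) else (H(pr) + H(pc)) / 2
  unname(mi / denom)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# clustering accuracy by exhaustive search over assignments (small k only)
acc_exhaustive <- function(true_labels, pred_labels) {
  tab <- table(true_labels, pred_labels)
  k <- max(dim(tab))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- 0
  for (perm in all_permutations(seq_len(k)))
    best <- max(best, sum(sq[cbind(seq_len(k), perm)]))
  best / length(true_labels)
}

# greedy matching: repeatedly take the largest remaining contingency cell
acc_greedy <- function(true_labels, pred_labels) {
  tab <- table(true_labels, pred_labels)
  k <- max(dim(tab))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  total <- 0
  for (step in seq_len(k)) {
    cell <- which(sq == max(sq), arr.ind = TRUE)[1, ]
    total <- total + sq[cell[1], cell[2]]
    sq[cell[1], ] <- -1
    sq[, cell[2]] <- -1
  }
  total / length(true_labels)
}

# informative-first / informative-last rankings for a synthetic dataset
oracle_ranking <- function(dataset) {
  p <- ncol(dataset$X)
  feature_ranking(colnames(dataset$X), rev(seq_len(p)) / p)
}
reversed_ranking <- function(dataset) {
  p <- ncol(dataset$X)
  feature_ranking(colnames(dataset$X), seq_len(p) / p)
}
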