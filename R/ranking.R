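#' Projected gradient field of one feature
#'
#' For feature `j`, evaluates at every training point the derivative of the
#' kernel row with respect to that coordinate and projects it onto the
#' retained kernel principal axes:
#' \deqn{w^j = \Big(\frac{dZ}{dt}\Big)^T
#'       \Big(I - \tfrac1n 1 1^T\Big)\, \tilde a,}
#' where the derivative vector has entries \eqn{D_j k(x_a, x_i)} over the
#' training points \eqn{x_i} (for the RBF kernel,
#' \eqn{-2\sigma k(x_a, x_i)(x_a^j - x_i^j)}). Stacking over all `n`
#' evaluation points gives the `n x q` matrix `W`: the direction of steepest
#' growth of feature `j` in the kernel PCA plot, one arrow per sample.
#'
#' Derivatives are taken with respect to the preprocessed (z-scored, when
#' `scale = TRUE` at fit time) coordinates, the space the kernel actually acts
#' on.
#'
#' @param model a fitted [kpca_fit()] model.
#' @param j feature index (1-based) or feature name.
#' @return An object of class `gradient_field`: list with `feature`, `j` and
#'   the `n x q` matrix `W`.
#' @export
gradient_projection <- function(model, j) {
  j <- resolve_feature(model, j)
  B <- centered_dual_coefs(model)
  xj <- model$X[, j]
  G <- switch(model$kernel$family,
    rbf    = -2 * model$kernel$sigma * model$K * outer(xj, xj, "-"),
    linear = matrix(xj, nrow = nrow(model$X), ncol = nrow(model$X), byrow = TRUE)
  )
  W <- G %*% B
  dimnames(W) <- list(model$sample_ids, paste0("KPC", seq_len(model$q)))
  structure(list(feature = model$feature_ids[j], j = j, W = W),
            class = "gradient_field")
}

resolve_feature <- function(model, j) {
  if (is.character(j)) {
    idx <- match(j, model$feature_ids)
    if (is.na(idx)) stop(sprintf("unknown feature '%s'", j), call. = FALSE)
    return(idx)
  }
  j <- as.integer(j)
  if (j < 1L || j > ncol(model$X))
    stop(sprintf("feature index %d out of range 1..%d", j, ncol(model$X)),
         call. = FALSE)
  j
}

# (I - 11'/n) %*% dual_coefs, the projection matrix the gradients hit
centered_dual_coefs <- function(model) {
  A <- model$dual_coefs
  sweep(A, 2, colMeans(A))
}

#' Score of one projected gradient field
#'
#' Per-sample norms \eqn{\|v_i^j\| = \sqrt{\sum_k w_{ik}^2}}, their mean (the
#' feature's importance score) and their sample standard deviation
#' (denominator `n - 1`).
#'
#' @param field a [gradient_projection()] result.
#' @return List with `score`, `sd` and the `n` per-sample `norms`.
#' @export
feature_score <- function(field) {
  if (!inherits(field, "gradient_field"))
    stop("'field' must be a gradient_field", call. = FALSE)
  norms <- sqrt(rowSums(field$W^2))
  list(score = mean(norms), sd = stats::sd(norms), norms = norms)
}

#' Rank all features by the norm of their projected kernel gradients
#'
#' Computes, for every feature `j`, the mean over training points of the norm
#' of the projection of the kernel's partial derivative onto the retained
#' kernel principal axes, and sorts features by that score (descending; ties
#' keep the original column order). This is the package's data-driven,
#' purely linear-algebraic feature importance for kernel PCA: a large score
#' means the feature moves the samples strongly in the retained axes.
#'
#' Features are processed in blocks so only `block_size * q` extra columns are
#' materialized at a time; results are identical to the per-feature
#' computation.
#'
#' @param model a fitted [kpca_fit()] model.
#' @param block_size features per block (memory/speed trade-off only).
#' @return A `feature_ranking` data frame with columns `rank`, `feature`,
#'   `score`, `sd` (sd of the per-sample norms), sorted by decreasing score.
#' @examples
#' d <- make_clustered_data(n = 40, p = 30, n_informative = 5, seed = 1)
#' m <- kpca_fit(d$X, rbf_kernel(1e-3), q = 2)
#' head(rank_features(m))
#' @export
rank_features <- function(model, block_size = 128L) {
  if (!inherits(model, "kpca_model"))
    stop("'model' must be a kpca_model", call. = FALSE)
  n <- nrow(model$X); p <- ncol(model$X); q <- model$q
  B <- centered_dual_coefs(model)
  if (model$kernel$family == "linear") {
    # every evaluation point sees the same derivative vector x_.j
    S <- crossprod(model$X, B)             # p x q, row j = x_j' B
    scores <- sqrt(rowSums(S^2))
    sds <- rep(0, p)
  } else {
    sigma <- model$kernel$sigma
    KB <- model$K %*% B                    # n x q, shared across features
    scores <- numeric(p)
    sds <- numeric(p)
    for (start in seq(1L, p, by = block_size)) {
      jj <- start:min(start + block_size - 1L, p)
      b <- length(jj)
      # columns (j,k): B[, k] * X[, j]; then K %*% M gives K diag(x_j) B
      M <- model$X[, jj, drop = FALSE][, rep(seq_len(b), each = q), drop = FALSE] *
        B[, rep(seq_len(q), times = b), drop = FALSE]
      TT <- model$K %*% M
      for (i in seq_len(b)) {
        cols <- (i - 1L) * q + seq_len(q)
        W <- -2 * sigma * (model$X[, jj[i]] * KB - TT[, cols, drop = FALSE])
        norms <- sqrt(rowSums(W^2))
        scores[jj[i]] <- mean(norms)
        sds[jj[i]] <- stats::sd(norms)
      }
    }
  }
  new_feature_ranking(model$feature_ids, scores, sds,
                      q = q, kernel = model$kernel, n = n)
}

#' Construct a feature ranking from scores
#'
#' Builds the ranking object used throughout the evaluation harness from raw
#' per-feature scores, e.g. to wrap an externally produced importance measure
#' for comparison. Features are sorted by decreasing score; ties keep the
#' input order.
#'
#' @param features character vector of feature ids.
#' @param scores numeric importance scores (same length).
#' @param sds optional per-feature standard deviations (default 0).
#' @return A `feature_ranking` data frame.
#' @export
feature_ranking <- function(features, scores, sds = rep(0, length(scores))) {
  if (length(features) != length(scores) || length(scores) != length(sds))
    stop("'features', 'scores' and 'sds' must have equal length", call. = FALSE)
  if (any(scores < 0)) stop("'scores' must be nonnegative", call. = FALSE)
  new_feature_ranking(as.character(features), as.numeric(scores),
                      as.numeric(sds))
}

new_feature_ranking <- function(features, scores, sds, q = NA, kernel = NULL,
                                n = NA) {
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(rank = seq_along(scores),
                    feature = features[ord],
                    score = scores[ord],
                    sd = sds[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, q = q, kernel = kernel, n_samples = n,
            class = c("feature_ranking", "data.frame"))
}

#' Top features of a ranking
#'
#' @param ranking a `feature_ranking`.
#' @param d how many features, from the top.
#' @return Character vector of feature names.
#' @export
top_features <- function(ranking, d) {
  if (!inherits(ranking, "feature_ranking"))
    stop("'ranking' must be a feature_ranking", call. = FALSE)
  ranking$feature[seq_len(min(d, nrow(ranking)))]
}

#' Write a feature ranking to a TSV file
#'
#' Emits columns `rank`, `feature`, `score`, `sd` (scores and sds multiplied
#' by `scale`; published tables often use `scale = 1000` for readability),
#' plus an optional `symbol` column merged from a two-column annotation table
#' (`feature`, `symbol`).
#'
#' @param ranking a `feature_ranking`.
#' @param path output file.
#' @param scale positive multiplier applied to `score` and `sd`.
#' @param top optionally restrict the output to the top `top` rows.
#' @param annotation optional data frame whose first two columns map feature
#'   ids to display symbols.
#' @return The written data frame, invisibly.
#' @export
write_ranking <- function(ranking, path, scale = 1, top = NULL,
                          annotation = NULL) {
  if (!is.numeric(scale) || scale <= 0) stop("'scale' must be > 0", call. = FALSE)
  out <- as.data.frame(ranking)
  if (!is.null(top)) out <- utils::head(out, top)
  out$score <- out$score * scale
  out$sd <- out$sd * scale
  if (!is.null(annotation)) {
    ann <- stats::setNames(as.data.frame(annotation)[, 1:2], c("feature", "symbol"))
    out$symbol <- ann$symbol[match(out$feature, ann$feature)]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a feature ranking written by [write_ranking()]
#'
#' Also accepts externally produced rankings: any delimited file with a
#' feature-id column and (optionally) score/sd columns.
#'
#' @param path TSV file with at least a `feature` column.
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"feature" %in% names(df))
    stop("ranking file must have a 'feature' column", call. = FALSE)
  score <- if ("score" %in% names(df)) df$score else rep(0, nrow(df))
  sd <- if ("sd" %in% names(df)) df$sd else rep(0, nrow(df))
  # preserve the file's order for equal scores
  new_feature_ranking(df$feature, score, sd)
}
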