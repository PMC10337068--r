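#' Generate clustered synthetic expression-like data
#'
#' Draws `n` samples from `n_clusters` Gaussian clusters with equal spherical
#' covariance (`noise_sd`). Only the first `n_informative` features carry
#' cluster structure: on those, the cluster means are equally spaced
#' `separation` apart (cluster c has mean `(c - 1) * separation`); all other
#' features are pure noise, independent of the labels. Cluster sizes are
#' balanced unless `proportions` is given. This mimics the situation the
#' feature ranking targets: a handful of structured variables buried among
#' thousands of irrelevant ones.
#'
#' Random draws use substreams derived from `seed`, so label assignment and
#' noise generation are independently reproducible.
#'
#' @param n samples.
#' @param p features (`>= n_informative`).
#' @param n_informative number of features carrying the cluster signal.
#' @param n_clusters number of groups (`<= n`).
#' @param separation between-cluster mean difference on informative features.
#' @param noise_sd Gaussian noise standard deviation on every feature.
#' @param proportions optional cluster proportions (length `n_clusters`,
#'   summing to 1); default balanced.
#' @param seed integer seed.
#' @return An object of class `synthetic_dataset`: list with `X` (named
#'   `n x p` matrix), `labels` (integer cluster ids), `informative` (indices
#'   of the structured features) and `params`.
#' @examples
#' d <- make_clustered_data(n = 60, p = 200, n_informative = 10,
#'                          n_clusters = 3, separation = 4, seed = 1)
#' table(d$labels)
#' @export
make_clustered_data <- function(n = 60, p = 200, n_informative = 10,
                                n_clusters = 3, separation = 4, noise_sd = 1,
                                proportions = NULL, seed = 1) {
  if (n_informative > p) stop("'n_informative' must be <= p", call. = FALSE)
  if (n_clusters > n) stop("'n_clusters' must be <= n", call. = FALSE)
  if (is.null(proportions)) proportions <- rep(1 / n_clusters, n_clusters)
  if (length(proportions) != n_clusters || abs(sum(proportions) - 1) > 1e-8)
    stop("'proportions' must have length n_clusters and sum to 1", call. = FALSE)
  sizes <- diff(round(cumsum(c(0, proportions)) * n))
  labels <- rep(seq_len(n_clusters), times = sizes)
  set.seed(derive_seed(seed, 1L))
  labels <- sample(labels)
  set.seed(derive_seed(seed, 2L))
  X <- matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  informative <- seq_len(n_informative)
  means <- (labels - 1) * separation
  X[, informative] <- X[, informative, drop = FALSE] + means
  dimnames(X) <- list(paste0("sample", seq_len(n)),
                      sprintf("f%04d", seq_len(p)))
  structure(list(X = X, labels = labels, informative = informative,
                 params = list(n = n, p = p, n_informative = n_informative,
                               n_clusters = n_clusters, separation = separation,
                               noise_sd = noise_sd, proportions = proportions,
                               seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic clustered dataset: %d samples x %d features, %d clusters,\n",
              p$n, p$p, p$n_clusters))
  cat(sprintf("  %d informative features (separation %g, noise sd %g), seed %d\n",
              p$n_informative, p$separation, p$noise_sd, p$seed))
  invisible(x)
}

#' Random feature ranking
#'
#' A uniformly random permutation of the features with constant
#' (uninformative) scores — the null ordering used to benchmark informative
#' rankings.
#'
#' @param p number of features.
#' @param seed integer seed.
#' @param feature_ids optional feature names (default `f0001`, ...).
#' @return A `feature_ranking` whose order is the random permutation.
#' @export
make_random_ranking <- function(p, seed = 1, feature_ids = NULL) {
  if (p < 1) stop("'p' must be >= 1", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- sprintf("f%04d", seq_len(p))
  set.seed(derive_seed(seed, 3L))
  perm <- sample.int(p)
  new_feature_ranking(feature_ids[perm], rep(0, p), rep(0, p))
}

# derive a substream seed below 2^31 from a base seed and stream ids
derive_seed <- function(seed, ...) {
  k <- c(as.integer(seed), as.integer(c(...)))
  s <- 0
  for (v in k) s <- (s * 69069 + v + 1) %% 2147483647
  as.integer(s)
}
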