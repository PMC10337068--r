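#' Clustering accuracy under optimal cluster-to-class matching
#'
#' The fraction of samples on which a predicted clustering agrees with the
#' true classes, maximized over all one-to-one assignments of predicted
#' cluster ids to class ids (solved as a linear sum assignment problem on the
#' contingency table). Invariant to any relabeling of either argument.
#'
#' @param true_labels,pred_labels equal-length label vectors (any atomic
#'   type; treated as categorical).
#' @return Accuracy in `[0, 1]`.
#' @export
clustering_accuracy <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop(sprintf("label length mismatch: %d vs %d",
                 length(true_labels), length(pred_labels)), call. = FALSE)
  if (length(true_labels) == 0) stop("empty labelings", call. = FALSE)
  tab <- table(true_labels, pred_labels)
  k <- max(dim(tab))
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  sol <- clue::solve_LSAP(sq, maximum = TRUE)
  sum(sq[cbind(seq_len(k), sol)]) / length(true_labels)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the geometric mean of the two partition
#' entropies (default), or their arithmetic mean. Conventions: terms with a
#' zero cell contribute 0; when both partitions are the identical
#' single-cluster labeling the value is 1; otherwise, if either partition has
#' zero entropy the value is 0.
#'
#' @inheritParams clustering_accuracy
#' @param variant `"geometric"` (default) or `"arithmetic"` normalization.
#' @return NMI in `[0, 1]`; symmetric in its arguments.
#' @export
normalized_mutual_information <- function(true_labels, pred_labels,
                                          variant = c("geometric", "arithmetic")) {
  variant <- match.arg(variant)
  if (length(true_labels) != length(pred_labels))
    stop(sprintf("label length mismatch: %d vs %d",
                 length(true_labels), length(pred_labels)), call. = FALSE)
  tab <- table(true_labels, pred_labels)
  n <- sum(tab)
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  hr <- -sum(ifelse(pr > 0, pr * log(pr), 0))
  hc <- -sum(ifelse(pc > 0, pc * log(pc), 0))
  pj <- tab / n
  expected <- outer(pr, pc)
  mi <- sum(ifelse(pj > 0, pj * log(pj / expected), 0))
  if (hr == 0 && hc == 0) return(1)          # both single-cluster: identical
  if (hr == 0 || hc == 0) return(0)
  denom <- if (variant == "geometric") sqrt(hr * hc) else (hr + hc) / 2
  min(max(mi / denom, 0), 1)
}

#' k-means evaluation of a feature ranking over nested subsets
#'
#' The standard unsupervised feature-selection benchmark: for each subset size
#' `d`, cluster the samples using only the top-`d` ranked features with
#' k-means (`k` = the true number of groups, a fresh random initialization per
#' run) and record the mean and standard deviation of clustering accuracy and
#' NMI against the true labels over `runs` repetitions.
#'
#' @param X sample-by-feature matrix.
#' @param true_labels length-`n` group labels.
#' @param ranking a `feature_ranking` over the columns of `X`.
#' @param d_grid subset sizes (each `<= ncol(X)`).
#' @param k number of clusters; defaults to the number of distinct true
#'   labels.
#' @param runs k-means repetitions per subset size.
#' @param nstart random initializations within each run (the best of which is
#'   kept by [stats::kmeans()]).
#' @param seed integer; each (d, run) pair gets a derived substream so the
#'   report is reproducible.
#' @param nmi_variant passed to [normalized_mutual_information()].
#' @return Data frame with one row per `d`: `acc_mean`, `acc_sd`, `nmi_mean`,
#'   `nmi_sd`; `runs` is recorded as an attribute.
#' @export
subset_kmeans_eval <- function(X, true_labels, ranking, d_grid, k = NULL,
                               runs = 20, nstart = 10, seed = 1,
                               nmi_variant = "geometric") {
  X <- as_data_matrix(X)
  if (is.null(k)) k <- length(unique(true_labels))
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  if (k > nrow(X)) stop("'k' exceeds the number of samples", call. = FALSE)
  if (max(d_grid) > ncol(X)) stop("subset size exceeds feature count", call. = FALSE)
  rows <- lapply(seq_along(d_grid), function(di) {
    d <- d_grid[di]
    Xd <- X[, top_features(ranking, d), drop = FALSE]
    acc <- nmi <- numeric(runs)
    for (r in seq_len(runs)) {
      set.seed(derive_seed(seed, di, r))
      # empty-cluster warnings from unlucky random starts are expected and
      # harmless: the best of the nstart initializations is kept
      km <- suppressWarnings(
        stats::kmeans(Xd, centers = k, nstart = nstart, iter.max = 100,
                      algorithm = "Lloyd"))
      acc[r] <- clustering_accuracy(true_labels, km$cluster)
      nmi[r] <- normalized_mutual_information(true_labels, km$cluster,
                                              variant = nmi_variant)
    }
    data.frame(d = d, acc_mean = mean(acc), acc_sd = stats::sd(acc),
               nmi_mean = mean(nmi), nmi_sd = stats::sd(nmi))
  })
  out <- do.call(rbind, rows)
  attr(out, "runs") <- runs
  attr(out, "k") <- k
  out
}

#' Silhouette of kernel PCA embeddings over nested feature subsets
#'
#' For each subset size `d`, refits kernel PCA on the top-`d` features of the
#' ranking (with the RBF bandwidth re-selected per subset by default, since
#' the distance scale changes with the feature count), clusters the `q`-dim
#' embedding with k-means, and records the mean silhouette width. The same
#' curve is computed for `random_rankings` seeded random feature orders, the
#' null the informative ranking should dominate.
#'
#' @param X sample-by-feature matrix.
#' @param ranking a `feature_ranking`.
#' @param subset_sizes feature counts to evaluate; sizes smaller than
#'   `n_clusters` are skipped with a warning.
#' @param n_clusters k-means cluster count for the silhouette.
#' @param q embedding dimension.
#' @param sigma `"select"` to re-run [select_sigma()] per subset, or a fixed
#'   positive number.
#' @param sigma_grid grid used when `sigma = "select"`.
#' @param random_rankings number of random-order null curves.
#' @param scale z-score features before the kernel.
#' @param seed integer seed for the random rankings and k-means starts.
#' @return Long data frame with columns `ranking` (`"ranked"` or
#'   `"random<i>"`), `d`, `sigma`, `silhouette`.
#' @export
silhouette_curve <- function(X, ranking, subset_sizes, n_clusters = 2, q = 2,
                             sigma = "select", sigma_grid = default_sigma_grid(),
                             random_rankings = 5, scale = TRUE, seed = 1) {
  X <- as_data_matrix(X)
  if (n_clusters < 2) stop("'n_clusters' must be >= 2", call. = FALSE)
  drop <- subset_sizes < n_clusters
  if (any(drop)) {
    warning(sprintf("skipping %d subset size(s) smaller than n_clusters",
                    sum(drop)), call. = FALSE)
    subset_sizes <- subset_sizes[!drop]
  }
  rankings <- c(list(ranked = ranking),
                stats::setNames(
                  lapply(seq_len(random_rankings), function(i)
                    make_random_ranking(ncol(X), seed = derive_seed(seed, 77L, i),
                                        feature_ids = colnames(X))),
                  if (random_rankings > 0) paste0("random", seq_len(random_rankings))
                  else character(0)))
  rows <- list()
  for (nm in names(rankings)) {
    for (d in subset_sizes) {
      Xd <- X[, top_features(rankings[[nm]], d), drop = FALSE]
      s <- if (identical(sigma, "select"))
        as.numeric(select_sigma(Xd, grid = sigma_grid, q = q, scale = scale))
      else as.numeric(sigma)
      m <- suppressWarnings(kpca_fit(Xd, rbf_kernel(s), q = q, scale = scale))
      set.seed(derive_seed(seed, match(nm, names(rankings)), d))
      km <- stats::kmeans(m$scores, centers = n_clusters, nstart = 5,
                          iter.max = 100)
      sil <- cluster::silhouette(km$cluster, stats::dist(m$scores))
      rows[[length(rows) + 1L]] <-
        data.frame(ranking = nm, d = d, sigma = s,
                   silhouette = mean(sil[, "sil_width"]))
    }
  }
  do.call(rbind, rows)
}

#' Train/test explained-variance curves over nested feature subsets
#'
#' Generalization check of the ranking: on each random train/test split, rank
#' features on the training set only, then for each subset size fit kernel
#' PCA separately on the training and on the test samples restricted to the
#' training-derived top-`d` features and compare the cumulative explained
#' variance of the first `q` components. Similar train and test curves mean
#' the selected features capture structure that generalizes.
#'
#' @param X sample-by-feature matrix.
#' @param subset_sizes feature counts to evaluate.
#' @param q components whose explained variance is summed.
#' @param splits number of random train/test splits.
#' @param train_fraction fraction of samples in the training set.
#' @param sigma `"select"` or a fixed positive bandwidth (used for both the
#'   ranking fit and the per-subset fits; re-selected per subset when
#'   `"select"`).
#' @param sigma_grid grid for `sigma = "select"`.
#' @param scale z-score features before the kernel.
#' @param seed integer seed driving the splits.
#' @return Data frame with columns `split`, `d`, `train_ev`, `test_ev`
#'   (cumulative explained-variance fractions).
#' @export
train_test_variance_curve <- function(X, subset_sizes, q = 2, splits = 5,
                                      train_fraction = 0.75, sigma = "select",
                                      sigma_grid = default_sigma_grid(),
                                      scale = TRUE, seed = 1) {
  X <- as_data_matrix(X)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must be in (0, 1)", call. = FALSE)
  n <- nrow(X)
  rows <- list()
  for (s in seq_len(splits)) {
    set.seed(derive_seed(seed, 11L, s))
    idx <- sample.int(n, size = round(train_fraction * n))
    Xtr <- X[idx, , drop = FALSE]
    Xte <- X[-idx, , drop = FALSE]
    sig_rank <- if (identical(sigma, "select"))
      as.numeric(select_sigma(Xtr, grid = sigma_grid, q = q, scale = scale))
    else as.numeric(sigma)
    mtr <- suppressWarnings(kpca_fit(Xtr, rbf_kernel(sig_rank), q = q, scale = scale))
    rk <- rank_features(mtr)
    for (d in subset_sizes) {
      feats <- top_features(rk, d)
      ev_of <- function(Xs) {
        sg <- if (identical(sigma, "select"))
          as.numeric(select_sigma(Xs[, feats, drop = FALSE],
                                  grid = sigma_grid, q = q, scale = scale))
        else as.numeric(sigma)
        m <- suppressWarnings(kpca_fit(Xs[, feats, drop = FALSE],
                                       rbf_kernel(sg), q = q, scale = scale))
        sum(explained_variance(m))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(split = s, d = d, train_ev = ev_of(Xtr), test_ev = ev_of(Xte))
    }
  }
  do.call(rbind, rows)
}
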