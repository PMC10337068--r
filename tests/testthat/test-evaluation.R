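test_that("clustering accuracy solves the optimal assignment and is relabeling-invariant", {
  truth <- rep(1:2, each = 6)
  pred <- c(rep(1, 5), 2, 1, 1, rep(2, 4))   # contingency [[5,1],[2,4]]
  expect_equal(clustering_accuracy(truth, pred), 9 / 12)
  expect_equal(clustering_accuracy(truth, truth), 1)
  expect_equal(clustering_accuracy(truth, 3 - truth), 1)  # permuted ids
  expect_error(clustering_accuracy(1:3, 1:4), "mismatch")

  set.seed(31)
  for (i in 1:20) {
    k1 <- sample(2:4, 1); k2 <- sample(2:4, 1); n <- 40
    t_lab <- sample(k1, n, replace = TRUE)
    p_lab <- sample(k2, n, replace = TRUE)
    acc <- clustering_accuracy(t_lab, p_lab)
    expect_equal(acc, acc_exhaustive(t_lab, p_lab))
    expect_gte(acc + 1e-12, acc_greedy(t_lab, p_lab))
    # invariance under relabeling of either argument
    relab <- sample(k2)
    expect_equal(clustering_accuracy(t_lab, relab[p_lab]), acc)
  }
})

test_that("NMI matches entropy arithmetic, is symmetric and handles degenerate partitions", {
  truth <- rep(1:2, each = 6)
  pred <- c(rep(1, 5), 2, 1, 1, rep(2, 4))
  tab <- table(truth, pred)
  expect_equal(normalized_mutual_information(truth, pred),
               nmi_from_table(tab))
  expect_equal(normalized_mutual_information(truth, pred, "arithmetic"),
               nmi_from_table(tab, "arithmetic"))
  expect_equal(normalized_mutual_information(truth, pred),
               normalized_mutual_information(pred, truth))
  expect_equal(normalized_mutual_information(truth, truth), 1)
  expect_equal(normalized_mutual_information(truth, rep(1, 12)), 0)
  expect_equal(normalized_mutual_information(rep(1, 5), rep(2, 5)), 1)
  set.seed(32)
  a <- sample(3, 30, replace = TRUE); b <- sample(4, 30, replace = TRUE)
  v <- normalized_mutual_information(a, b)
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("subset k-means evaluation is reproducible and full-subset equals full-matrix clustering", {
  d <- make_clustered_data(n = 40, p = 20, n_informative = 5, n_clusters = 2,
                           separation = 5, seed = 4)
  rk <- oracle_ranking(d)
  r1 <- subset_kmeans_eval(d$X, d$labels, rk, d_grid = c(5, 20), runs = 3, seed = 9)
  r2 <- subset_kmeans_eval(d$X, d$labels, rk, d_grid = c(5, 20), runs = 3, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1$acc_mean >= 0 & r1$acc_mean <= 1))
  expect_true(all(r1$nmi_mean >= 0 & r1$nmi_mean <= 1))
  expect_true(all(r1$acc_sd >= 0))
  # d = p: the subset is the full matrix, so any ranking gives the same result
  rr <- make_random_ranking(20, seed = 5, feature_ids = colnames(d$X))
  full1 <- subset_kmeans_eval(d$X, d$labels, rk, d_grid = 20, runs = 2, seed = 9)
  full2 <- subset_kmeans_eval(d$X, d$labels, rr, d_grid = 20, runs = 2, seed = 9)
  expect_equal(full1$acc_mean, full2$acc_mean)
  expect_error(subset_kmeans_eval(d$X, d$labels, rk, d_grid = 5, k = 50), "samples")
  expect_error(subset_kmeans_eval(d$X, d$labels, rk, d_grid = 30), "exceeds")
})

test_that("well-separated clusters give perfect accuracy on informative subsets", {
  d <- make_clustered_data(n = 45, p = 30, n_informative = 6, n_clusters = 3,
                           separation = 8, noise_sd = 1, seed = 6)
  res <- subset_kmeans_eval(d$X, d$labels, oracle_ranking(d),
                            d_grid = c(6, 10), runs = 5, seed = 2)
  expect_equal(res$acc_mean, c(1, 1))
  expect_equal(res$nmi_mean, c(1, 1))
})

test_that("silhouette curves favour informative subsets and respect skip rules", {
  d <- make_clustered_data(n = 30, p = 30, n_informative = 5, n_clusters = 2,
                           separation = 6, seed = 7)
  expect_warning(
    sc <- silhouette_curve(d$X, oracle_ranking(d), subset_sizes = c(1, 5, 15),
                           n_clusters = 2, q = 2, random_rankings = 1, seed = 3),
    "skipping")
  expect_setequal(unique(sc$d), c(5, 15))
  ranked5 <- sc$silhouette[sc$ranking == "ranked" & sc$d == 5]
  expect_gt(ranked5, 0.8)   # clear separation on the informative features
  # i.i.d. noise: silhouette stays low whatever the ranking
  noise <- make_clustered_data(n = 30, p = 30, n_informative = 5,
                               n_clusters = 2, separation = 0, seed = 8)
  scn <- silhouette_curve(noise$X, oracle_ranking(noise), subset_sizes = 15,
                          n_clusters = 2, q = 2, random_rankings = 0, seed = 3)
  expect_lt(scn$silhouette, 0.5)
})

test_that("train/test variance curves use the full matrix at d = p and identical data give identical curves", {
  d <- make_clustered_data(n = 40, p = 25, n_informative = 5, n_clusters = 2,
                           separation = 5, seed = 9)
  tv <- train_test_variance_curve(d$X, subset_sizes = c(5, 25), q = 2,
                                  splits = 2, train_fraction = 0.5,
                                  sigma = 1e-4, seed = 4)
  expect_equal(nrow(tv), 4)
  expect_true(all(tv$train_ev > 0 & tv$train_ev <= 1))
  expect_true(all(tv$test_ev > 0 & tv$test_ev <= 1))
  expect_error(train_test_variance_curve(d$X, 5, train_fraction = 1.2), "0, 1")
})
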