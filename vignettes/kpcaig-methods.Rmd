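---
title: "Gradient-based feature importance for kernel PCA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-based feature importance for kernel PCA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kpcaig)
```

## The problem

Kernel PCA embeds samples through a kernel function and diagonalizes the
centered Gram matrix; the embedding can capture nonlinear structure that
ordinary PCA misses, which is valuable for expression matrices where the
number of features far exceeds the number of samples. The price is
interpretability: the principal axes live in an implicit feature space, the
original variables disappear into pairwise similarities, and the pre-image of
an embedded point generally does not exist. This package ranks the original
features directly on the fitted embedding, with nothing but linear algebra:
no permutations, no optimization, no pre-image reconstruction.

## Model and procedure

Given samples $x_1, \dots, x_n \in \mathbb{R}^p$ and a kernel $k$, the Gram
matrix $K_{ij} = k(x_i, x_j)$ is double-centered,

$$\tilde K = K - \tfrac1n K \mathbf{1}\mathbf{1}^T
           - \tfrac1n \mathbf{1}\mathbf{1}^T K
           + \tfrac1{n^2}(\mathbf{1}^T K \mathbf{1})\mathbf{1}\mathbf{1}^T,$$

and eigendecomposed. With eigenpairs $(\lambda_k, e_k)$ of $\tilde K$, the
dual coefficients are $\tilde a^k = e_k / \sqrt{\lambda_k}$, which makes each
axis $\tilde v^k = \sum_i \tilde a^k_i \phi(x_i)$ unit-norm in feature space
($\tilde a^{kT} \tilde K \tilde a^k = 1$). A point $x$ with kernel row
$Z = (k(x, x_i))_i$ projects to

$$\rho(x) = \Big(Z^T - \tfrac1n \mathbf{1}^T K\Big)
            \Big(I - \tfrac1n \mathbf{1}\mathbf{1}^T\Big) \tilde A,$$

where $\tilde A$ stacks the retained dual-coefficient columns.

**The importance score.** Moving $x$ along coordinate $j$ moves $\rho(x)$;
the velocity of that motion in the embedding is the derivative of the
projection along coordinate $j$. Because the centering terms are constant in
$x$, this is

$$w^j(x) = \Big(\tfrac{\partial Z}{\partial x^j}\Big)^T
           \Big(I - \tfrac1n \mathbf{1}\mathbf{1}^T\Big) \tilde A,
  \qquad
  \Big(\tfrac{\partial Z}{\partial x^j}\Big)_i = D_j k(x, x_i).$$

For the radial basis kernel $k(x, y) = \exp(-\sigma \|x - y\|^2)$ the
derivative has the closed form $D_j k(x, x_i) = -2\sigma\,k(x, x_i)\,
(x^j - x^j_i)$; for the linear kernel it is simply $x^j_i$. Evaluating
$w^j$ at every training point gives an $n \times q$ matrix $W^j$ — one
arrow per sample, drawn by `variable_arrow_field()`. The score of feature
$j$ is the mean length of those arrows,

$$r^j = \frac1n \sum_{i=1}^n \Big(\sum_{k=1}^q (W^j_{ik})^2\Big)^{1/2},$$

and `rank_features()` sorts all $p$ features by $r^j$. A large score means
the feature moves samples strongly within the retained axes; a feature the
embedding ignores scores near zero, and an exactly constant feature scores
exactly zero. The reported `sd` column is the sample standard deviation
(denominator $n-1$) of the $n$ per-sample arrow lengths; it measures how
localized a feature's influence is (for the linear kernel all arrows are
identical and the sd is exactly zero). The per-sample norms themselves are
available through `feature_score(gradient_projection(model, j))`.

Two conventions pin the absolute score scale and must be kept in mind when
comparing numbers across software: the axis normalization
($\|\tilde v^k\| = 1$, enforced here) and the RBF parameterization ($\sigma$
multiplies the squared distance; some implementations use
$1/(2\sigma^2)$). Scores scale linearly with the axis norm, so both are fixed
by design. Published tables often multiply scores by $10^3$ for readability;
`write_ranking(..., scale = 1000)` reproduces that convention without
changing the ranking.

## Tunable parameters

* **`sigma`** (RBF bandwidth, inverse squared-distance units). The only
  truly sensitive parameter. `select_sigma()` implements a grid heuristic:
  pick the bandwidth maximizing the cumulative explained variance of the
  first `q` components, ties going to the smaller value. The default grid is
  13 log-spaced values in $[10^{-8}, 10^{-2}]$, bracketing what z-scored
  matrices from tens to tens of thousands of features require (squared
  distances grow linearly in $p$, so the appropriate $\sigma$ shrinks
  accordingly; $10^{-5}$ is typical for a 5·10^4-feature microarray matrix).
* **`q`** (retained components). There is no automatic cutoff: the score
  deliberately measures influence *on the axes you chose to look at*, so `q`
  is a required analysis decision (2–5 in practice), recorded in the model
  and the run manifest.
* **`scale`** (default `TRUE`): per-feature z-scoring before the kernel.
  Without it, high-variance features dominate every squared distance.
  Zero-variance features are centered to zero, not divided (with a warning).
* **`block_size`** in `rank_features()` trades memory for speed only; the
  blocked result is bit-identical to the one-shot computation.

## Numerical choices

* Eigenvalues below `eig_tol` ($10^{-12}$ relative) are treated as zero
  rank; `q` is capped to the numerical rank with a warning. Rank deficiency
  is the norm when $n$ exceeds the effective dimension (duplicated samples,
  linear kernels with $p < n$).
* Eigenvector signs are arbitrary; each dual-coefficient column is flipped
  so its largest-magnitude entry is positive. This makes scores, plots and
  archives reproducible run to run, and sample-order permutations reorder
  scores without changing them.
* Gram symmetry is enforced by construction (symmetrized squared distances,
  `tcrossprod`), not by post-hoc averaging; RBF diagonals are exactly 1.
* Score ties (duplicated columns) are broken by original column order.
* Explained-variance fractions divide by the sum of *all* nonnegative
  eigenvalues of $\tilde K$, not just the retained ones, so they do not
  inflate when `q` is small.

## The synthetic-data generator

`make_clustered_data()` draws Gaussian clusters with equal spherical
covariance; only the first `n_informative` features carry the cluster
signal, with equally spaced cluster means `separation` apart, and all other
features are label-independent noise. Defaults (n = 60, p = 200, 10
informative features, 3 clusters, separation 4, unit noise) give a
moderately hard recovery problem: cluster structure is invisible in any
single noise feature but clear in the informative subspace. This emulates
the shape of the expression matrices the method targets — $n \ll p$, a
small structured subspace, exchangeable noise — and deliberately omits what
real microarray data adds on top: heavy-tailed and correlated noise, probe
effects, batch structure, nonlinear manifolds. Tests passing on this
generator therefore validate the algebra and the protocol, not robustness
to those artifacts.

Evaluation problem sizes were chosen once to match the structure each check
needs: recovery and silhouette checks run on the generator defaults; the
train/test explained-variance comparison runs on a 257-sample fixture split
192/65 five times, matching the reference protocol for that comparison —
explained-variance fractions carry a strong sample-count dependence (the
denominator is a sum over a rank-$(n-1)$ spectrum), so comparing fits of 45
versus 15 samples would measure that estimator bias rather than
generalization of the selected features.

## The evaluation harness

* **Clustering accuracy** maximizes agreement over one-to-one
  cluster-to-class assignments, solved exactly as a linear sum assignment
  problem (`clue::solve_LSAP`); greedy matching can be strictly worse and is
  only used as a lower-bound oracle in tests.
* **NMI** is normalized by the geometric mean of the partition entropies by
  default (the common convention in the unsupervised feature-selection
  literature); an arithmetic-mean variant is available. Degenerate cases:
  two identical single-cluster partitions give 1, any other zero-entropy
  partition gives 0.
* **k-means** always uses the true number of groups, Lloyd iterations and 10
  random initializations per run, seeded per (subset size, run).
* **Silhouette curves** refit the embedding per feature subset, re-selecting
  $\sigma$ by default because the appropriate bandwidth changes with the
  feature count; a fixed-$\sigma$ mode exists for speed. Subsets smaller
  than the cluster count are skipped with a warning.
* External rankings (from any other method) can enter the same harness via
  `feature_ranking()` or `read_ranking()`.

```{r example}
d <- make_clustered_data(n = 60, p = 200, n_informative = 10, n_clusters = 3,
                         separation = 4, noise_sd = 1, seed = 1)
sigma <- select_sigma(d$X, q = 3)
model <- kpca_fit(d$X, rbf_kernel(as.numeric(sigma)), q = 3)
ranking <- rank_features(model)
head(ranking, 12)
sum(top_features(ranking, 10) %in% colnames(d$X)[d$informative])
```

## Known limitations

* Scores are relative, not inferential: there is no null distribution, no
  significance threshold, and no automatic choice of how many features to
  keep. The score-distribution plot is the intended selection aid.
* Only kernels with analytic first derivatives are supported (RBF and
  linear here); the framework extends to any such kernel, but score
  magnitudes are not comparable across kernel families.
* Derivatives are taken in the preprocessed (z-scored) coordinates; scores
  answer "how much does a one-sd change move the embedding", which is
  usually what is wanted, but it is a convention.
* The Gram matrix is dense ($n \times n$); the implementation assumes
  $n$ is the small dimension, as in expression data. Ranking cost is
  $O(p\,n^2 q)$, linear in $p$.
* Out-of-sample projection of a point far from all training samples decays
  to the projection of the training mean, an intrinsic property of RBF
  embeddings rather than a defect of the score.
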