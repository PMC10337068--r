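#' Kernel specifications
#'
#' Constructors for the kernel families understood by the package. A kernel
#' spec is a small list carrying the family name and its hyperparameters; every
#' family must supply both the kernel value and its first partial derivative
#' with respect to a coordinate of the first argument, which is what the
#' gradient-based feature ranking differentiates.
#'
#' The radial basis (Gaussian) kernel is parameterized as
#' \deqn{k(x, y) = \exp(-\sigma \|x - y\|^2),}
#' i.e. `sigma` multiplies the *squared* Euclidean distance directly (not the
#' \eqn{1/(2\sigma^2)} convention). This matters when plugging in published
#' bandwidths such as `sigma = 1e-5` for microarray-scale data.
#'
#' @param sigma positive bandwidth of the RBF kernel.
#' @return An object of class `kernel_spec`.
#' @examples
#' k <- rbf_kernel(0.5)
#' kernel_value(k, c(0, 0), c(1, 1))  # exp(-1)
#' @export
rbf_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive finite number", call. = FALSE)
  structure(list(family = "rbf", sigma = as.numeric(sigma)), class = "kernel_spec")
}

#' @rdname rbf_kernel
#' @export
linear_kernel <- function() {
  structure(list(family = "linear"), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$family == "rbf")
    cat(sprintf("RBF kernel: k(x, y) = exp(-%g * ||x - y||^2)\n", x$sigma))
  else
    cat("Linear kernel: k(x, y) = <x, y>\n")
  invisible(x)
}

stopifnot_kernel_spec <- function(spec) {
  if (!inherits(spec, "kernel_spec"))
    stop("'kernel' must be a kernel_spec (see rbf_kernel(), linear_kernel())",
         call. = FALSE)
  invisible(spec)
}

#' Evaluate a kernel between two points
#'
#' @param spec a [rbf_kernel()] or [linear_kernel()] specification.
#' @param x,y numeric vectors of equal length.
#' @return The scalar kernel value; for the RBF family a number in `(0, 1]`.
#' @export
kernel_value <- function(spec, x, y) {
  stopifnot_kernel_spec(spec)
  if (length(x) != length(y))
    stop(sprintf("dimension mismatch: length(x) = %d, length(y) = %d",
                 length(x), length(y)), call. = FALSE)
  switch(spec$family,
    rbf    = exp(-spec$sigma * sum((x - y)^2)),
    linear = sum(x * y)
  )
}

#' Partial derivative of a kernel with respect to one coordinate
#'
#' Returns \eqn{\partial k(x, x_i) / \partial x^j}, the derivative with respect
#' to the j-th coordinate of the *first* argument. For the RBF kernel this is
#' the closed form \eqn{-2\sigma\, k(x, x_i)\,(x^j - x_i^j)}; for the linear
#' kernel it is \eqn{x_i^j}.
#'
#' @inheritParams kernel_value
#' @param x_i the (training) point the kernel is evaluated against.
#' @param j coordinate index in `1..length(x)`.
#' @export
kernel_derivative <- function(spec, x, x_i, j) {
  stopifnot_kernel_spec(spec)
  if (length(x) != length(x_i))
    stop(sprintf("dimension mismatch: length(x) = %d, length(x_i) = %d",
                 length(x), length(x_i)), call. = FALSE)
  if (j < 1L || j > length(x))
    stop(sprintf("feature index j = %d out of range 1..%d", j, length(x)),
         call. = FALSE)
  switch(spec$family,
    rbf    = -2 * spec$sigma * kernel_value(spec, x, x_i) * (x[j] - x_i[j]),
    linear = x_i[j]
  )
}

#' Gram matrix of a data set
#'
#' Computes the `n x n` matrix of pairwise kernel values between the rows of
#' `X` (samples). Symmetry is exact by construction: pairwise squared
#' distances are symmetrized before exponentiation and the linear kernel is
#' `tcrossprod`.
#'
#' @param X numeric sample-by-feature matrix with at least two rows; all
#'   entries must be finite.
#' @param spec a `kernel_spec`.
#' @param Y optional second matrix (same features); when given, the
#'   `nrow(Y) x nrow(X)` cross-kernel matrix is returned instead.
#' @return A symmetric kernel matrix with `dimnames` taken from the row names
#'   of the inputs; for the RBF family the diagonal is exactly 1.
#' @export
kernel_matrix <- function(X, spec, Y = NULL) {
  stopifnot_kernel_spec(spec)
  X <- as.matrix(X)
  if (is.null(Y) && nrow(X) < 2L)
    stop("need at least 2 samples to build a kernel matrix", call. = FALSE)
  check_finite_matrix(X, "X")
  if (is.null(Y)) {
    K <- switch(spec$family,
      rbf = {
        D2 <- squared_distances(X, X)
        # numerical symmetrization of the distances, not of exp(.)
        D2 <- (D2 + t(D2)) / 2
        diag(D2) <- 0
        exp(-spec$sigma * D2)
      },
      linear = tcrossprod(X)
    )
    dimnames(K) <- list(rownames(X), rownames(X))
  } else {
    Y <- as.matrix(Y)
    check_finite_matrix(Y, "Y")
    if (ncol(Y) != ncol(X))
      stop(sprintf("feature mismatch: X has %d columns, Y has %d", ncol(X), ncol(Y)),
           call. = FALSE)
    K <- switch(spec$family,
      rbf    = exp(-spec$sigma * squared_distances(Y, X)),
      linear = tcrossprod(Y, X)
    )
    dimnames(K) <- list(rownames(Y), rownames(X))
  }
  K
}

# pairwise squared Euclidean distances between rows of A (m x p) and B (n x p)
squared_distances <- function(A, B) {
  m <- rowSums(A^2)
  n <- rowSums(B^2)
  D2 <- outer(m, n, "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0  # guard tiny negative round-off
  D2
}

check_finite_matrix <- function(X, name) {
  if (!is.numeric(X))
    stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  if (!all(is.finite(X))) {
    bad <- which(!apply(is.finite(X), 2, all))
    ids <- if (!is.null(colnames(X))) colnames(X)[bad] else as.character(bad)
    stop(sprintf("non-finite values in '%s' (features: %s)", name,
                 paste(utils::head(ids, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(X)
}
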