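#' Kernel specification
#'
#' Describes the basis used by an RVM: either the raw-feature linear basis
#' (one design column per marker plus an intercept) or one of the standard
#' kernel families evaluated between pairs of individuals.
#'
#' @param family One of `"linear_basis"`, `"linear"`, `"polynomial"`,
#'   `"gaussian"`. `"linear"` is the linear kernel, i.e. a polynomial kernel
#'   with `c = 0`, `d = 1`.
#' @param gamma Positive bandwidth of the Gaussian kernel
#'   `K(x, x') = exp(-gamma * ||x - x'||^2)`. Required for `"gaussian"`,
#'   ignored otherwise.
#' @param c Non-negative offset of the polynomial kernel
#'   `K(x, x') = (x . x' + c)^d`.
#' @param d Positive integer degree of the polynomial kernel.
#'
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("gaussian", gamma = 2e-4)
#' kernel_spec("polynomial", c = 1, d = 2)
#' @export
kernel_spec <- function(family = c("linear_basis", "linear", "polynomial", "gaussian"),
                        gamma = NULL, c = 0, d = 1L) {
  family <- match.arg(family)
  if (family == "gaussian") {
    if (is.null(gamma) || !is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
      stop("gaussian kernel requires a single gamma > 0", call. = FALSE)
  } else {
    gamma <- NULL
  }
  if (family == "polynomial") {
    if (!is.numeric(c) || length(c) != 1L || c < 0)
      stop("polynomial kernel requires c >= 0", call. = FALSE)
    d <- as.integer(d)
    if (is.na(d) || d < 1L) stop("polynomial kernel requires integer degree d >= 1", call. = FALSE)
  } else {
    c <- 0
    d <- 1L
  }
  structure(list(family = family, gamma = gamma, c = c, d = d),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec>", kernel_label(x), "\n")
  invisible(x)
}

#' Short human-readable label for a kernel specification
#'
#' @param spec A [kernel_spec()].
#' @return A single string such as `"gaussian(gamma=2e-04)"`.
#' @export
kernel_label <- function(spec) {
  switch(spec$family,
    linear_basis = "linear_basis",
    linear       = "linear",
    polynomial   = sprintf("polynomial(c=%g, d=%d)", spec$c, spec$d),
    gaussian     = sprintf("gaussian(gamma=%g)", spec$gamma)
  )
}

#' Evaluate a kernel between two vectors
#'
#' @param x,x2 Numeric vectors of equal length.
#' @param spec A [kernel_spec()] with a kernel family (not `"linear_basis"`).
#' @return The scalar kernel value.
#' @examples
#' kernel_value(c(1, 0), c(0, 1), kernel_spec("linear"))
#' @export
kernel_value <- function(x, x2, spec) {
  if (length(x) != length(x2))
    stop("kernel_value: vectors have different lengths (", length(x), " vs ",
         length(x2), ")", call. = FALSE)
  if (spec$family == "linear_basis")
    stop("linear_basis is not a kernel; use build_design_matrix()", call. = FALSE)
  switch(spec$family,
    linear     = sum(x * x2),
    polynomial = (sum(x * x2) + spec$c)^spec$d,
    gaussian   = exp(-spec$gamma * sum((x - x2)^2))
  )
}

#' Compute a Gram (kernel) matrix between two sets of rows
#'
#' Vectorized pairwise evaluation: entry (i, j) equals
#' `kernel_value(X[i, ], Y[j, ], spec)`.
#'
#' @param X Numeric matrix, N x M.
#' @param Y Numeric matrix, Q x M (defaults to `X`).
#' @param spec A [kernel_spec()] with a kernel family.
#' @return An N x Q numeric matrix.
#' @export
kernel_matrix <- function(X, Y = X, spec) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    stop("kernel_matrix: X and Y have different numbers of columns", call. = FALSE)
  if (spec$family == "linear_basis")
    stop("linear_basis is not a kernel; use build_design_matrix()", call. = FALSE)
  G <- tcrossprod(X, Y)
  switch(spec$family,
    linear     = G,
    polynomial = (G + spec$c)^spec$d,
    gaussian   = {
      # ||x - y||^2 = ||x||^2 + ||y||^2 - 2 x.y; clamp tiny negatives from
      # floating-point cancellation so the diagonal is exactly 1 when X == Y
      d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * G
      d2[d2 < 0] <- 0
      exp(-spec$gamma * d2)
    }
  )
}

#' Default Gaussian bandwidth grid for model selection
#'
#' @return Numeric vector `c(1e-4, 2e-4, 3e-4)`, the default grid searched
#'   when selecting a Gaussian kernel RVM.
#' @export
default_gamma_grid <- function() c(1e-4, 2e-4, 3e-4)
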