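#' Build the RVM design matrix
#'
#' In basis mode the design is the N x (M + 1) matrix whose first column is
#' the intercept (all ones) and whose remaining columns are the raw 0/1
#' marker genotypes, so that pruning acts on markers. In kernel mode the
#' design is the N x N Gram matrix with one column per training individual
#' (plus an optional leading intercept column).
#'
#' @param X Genotype matrix, N individuals x M markers. Basis mode requires
#'   strictly 0/1 entries; kernel mode accepts any reals.
#' @param spec A [kernel_spec()].
#' @param include_kernel_intercept Prepend an all-ones column to the Gram
#'   matrix (kernel mode only). Default `FALSE`: the kernel expansion has no
#'   bias term.
#' @return A numeric matrix with attributes `basis_kind`
#'   (`"linear_basis"` or `"kernel"`) and `column_meaning` (`"intercept"`,
#'   `"feature"` or `"training_point"` per column).
#' @export
build_design_matrix <- function(X, spec, include_kernel_intercept = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L || ncol(X) < 1L)
    stop("build_design_matrix: need at least 2 individuals and 1 marker", call. = FALSE)
  if (any(!is.finite(X)))
    stop("build_design_matrix: genotype matrix contains non-finite values", call. = FALSE)
  if (spec$family == "linear_basis") {
    bad <- which(!(X == 0 | X == 1))
    if (length(bad))
      stop("build_design_matrix: basis mode requires {0,1} genotypes; ",
           length(bad), " offending cells, first at [",
           paste(arrayInd(bad[1L], dim(X)), collapse = ","), "]", call. = FALSE)
    Phi <- cbind(1, X)
    attr(Phi, "basis_kind") <- "linear_basis"
    attr(Phi, "column_meaning") <- c("intercept", rep("feature", ncol(X)))
  } else {
    K <- kernel_matrix(X, X, spec)
    Phi <- if (include_kernel_intercept) cbind(1, K) else K
    attr(Phi, "basis_kind") <- "kernel"
    attr(Phi, "column_meaning") <-
      c(if (include_kernel_intercept) "intercept",
        rep("training_point", nrow(X)))
  }
  dimnames(Phi) <- NULL
  Phi
}

# Cholesky factor of H = sigma^-2 Phi'Phi + diag(alpha) with one jitter
# retry; failure after the retry signals genuine ill-conditioning.
.chol_with_jitter <- function(H) {
  U <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(U)) {
    jitter <- 1e-10 * sum(diag(H)) / nrow(H)
    U <- tryCatch(chol(H + diag(jitter, nrow(H))), error = function(e) NULL)
    if (is.null(U))
      stop("posterior_stats: Cholesky factorization failed even with jitter; ",
           "the active system is ill-conditioned", call. = FALSE)
  }
  U
}

#' Posterior covariance and mean of the RVM weights
#'
#' Computes `Sigma = (sigma^-2 Phi'Phi + A)^-1` and
#' `mu = sigma^-2 Sigma Phi' t` for the active columns, via a Cholesky
#' factorization of the symmetric positive-definite system (never a generic
#' inverse). A failed factorization is retried once with diagonal jitter
#' `1e-10 * trace/k`.
#'
#' @param Phi_active N x k design matrix restricted to active columns.
#' @param t Length-N target vector.
#' @param alpha Length-k vector of positive weight precisions.
#' @param sigma2 Positive noise variance.
#' @return List with `Sigma` (k x k), `mu` (length k), and the internal
#'   Cholesky factor `chol_H` reused by the marginal-likelihood computation.
#' @export
posterior_stats <- function(Phi_active, t, alpha, sigma2) {
  Phi_active <- as.matrix(Phi_active)
  k <- ncol(Phi_active)
  stopifnot(k >= 1L, length(alpha) == k, length(t) == nrow(Phi_active))
  if (any(alpha <= 0) || any(!is.finite(alpha)))
    stop("posterior_stats: alpha must be finite and > 0", call. = FALSE)
  if (sigma2 <= 0) stop("posterior_stats: sigma2 must be > 0", call. = FALSE)
  H <- crossprod(Phi_active) / sigma2
  diag(H) <- diag(H) + alpha
  U <- .chol_with_jitter(H)
  Sigma <- chol2inv(U)
  Sigma <- (Sigma + t(Sigma)) / 2
  mu <- drop(Sigma %*% crossprod(Phi_active, t)) / sigma2
  list(Sigma = Sigma, mu = mu, chol_H = U)
}

# Posterior quantities for the fit loop. When the active set is larger
# than N, the k x k system is solved through its N x N dual
# C = sigma2 I + Phi A^-1 Phi' (Woodbury), which gives mu, diag(Sigma),
# log|C| and t'C^-1 t at O(N^2 k) instead of O(k^3); otherwise the
# primal H = A + sigma^-2 Phi'Phi factorization is used. Both paths give
# the same quantities up to rounding.
.posterior_core <- function(Phi_active, t, alpha, sigma2) {
  n <- nrow(Phi_active); k <- ncol(Phi_active)
  if (k <= n) {
    H <- crossprod(Phi_active) / sigma2
    diag(H) <- diag(H) + alpha
    U <- .chol_with_jitter(H)
    Sigma <- chol2inv(U)
    mu <- drop(Sigma %*% crossprod(Phi_active, t)) / sigma2
    logdet_C <- n * log(sigma2) - sum(log(alpha)) + 2 * sum(log(diag(U)))
    quad <- (sum(t^2) - sum(t * drop(Phi_active %*% mu))) / sigma2
    list(mu = mu, Sigma_diag = diag(Sigma), logdet_C = logdet_C, quad = quad)
  } else {
    B <- sweep(Phi_active, 2L, sqrt(alpha), `/`)
    C <- tcrossprod(B)
    diag(C) <- diag(C) + sigma2
    U <- .chol_with_jitter(C)
    Cinv_t <- backsolve(U, forwardsolve(t(U), t))
    mu <- drop(crossprod(Phi_active, Cinv_t)) / alpha
    V <- backsolve(U, forwardsolve(t(U), Phi_active))
    Sigma_diag <- 1 / alpha - colSums(Phi_active * V) / alpha^2
    list(mu = mu, Sigma_diag = Sigma_diag,
         logdet_C = 2 * sum(log(diag(U))),
         quad = sum(t * Cinv_t))
  }
}

#' Type-II maximum-likelihood hyperparameter re-estimation
#'
#' One full-batch update of the weight precisions and the noise variance:
#' `alpha_i <- (1 - alpha_i * Sigma_ii) / mu_i^2` and
#' `sigma2 <- ||t - Phi mu||^2 / (N - sum_i (1 - alpha_i * Sigma_ii))`,
#' using the squared residual norm. Entries whose update is non-positive or
#' non-finite (including `mu_i = 0`) are set to `prune_threshold` so the
#' caller removes them.
#'
#' @param Phi_active N x k active design matrix.
#' @param t Length-N target vector.
#' @param alpha,sigma2 Current hyperparameters.
#' @param Sigma,mu Posterior statistics from [posterior_stats()]; `Sigma`
#'   may be the full covariance matrix or just its diagonal.
#' @param prune_threshold Precision value at and above which a basis
#'   function is considered pruned.
#' @param sigma2_min Lower clamp for the noise variance.
#' @return List with `alpha` (length k), `sigma2`, and `gamma` (the
#'   well-determinedness factors `1 - alpha_i * Sigma_ii`).
#' @export
update_hyperparameters <- function(Phi_active, t, alpha, sigma2, Sigma, mu,
                                   prune_threshold = 1e12, sigma2_min = 0) {
  sigma_diag <- if (is.matrix(Sigma)) diag(Sigma) else Sigma
  gamma <- 1 - alpha * sigma_diag
  alpha_new <- gamma / mu^2
  bad <- !is.finite(alpha_new) | alpha_new <= 0
  alpha_new[bad] <- prune_threshold
  alpha_new <- pmin(alpha_new, prune_threshold)

  n <- length(t)
  denom <- n - sum(gamma)
  if (denom <= 0)
    stop("update_hyperparameters: degenerate fit, effective degrees of freedom ",
         "consume all ", n, " observations", call. = FALSE)
  resid <- t - drop(as.matrix(Phi_active) %*% mu)
  sigma2_new <- max(sum(resid^2) / denom, sigma2_min)
  list(alpha = alpha_new, sigma2 = sigma2_new, gamma = gamma)
}

#' Log marginal likelihood of the RVM hyperparameters
#'
#' Evaluates `log N(t | 0, C)` with `C = sigma2 I + Phi A^-1 Phi'` through
#' the determinant and inversion identities on the k x k active system
#' (cost O(N k^2)); C itself is never formed.
#'
#' @inheritParams posterior_stats
#' @param stats Optional result of [posterior_stats()] for the same
#'   arguments, to avoid refactorizing.
#' @return The scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(Phi_active, t, alpha, sigma2, stats = NULL) {
  Phi_active <- as.matrix(Phi_active)
  n <- length(t)
  if (is.null(stats)) stats <- posterior_stats(Phi_active, t, alpha, sigma2)
  # log|C| = N log sigma2 - sum log alpha + log|H|,  H = A + sigma^-2 Phi'Phi
  logdet_H <- 2 * sum(log(diag(stats$chol_H)))
  logdet_C <- n * log(sigma2) - sum(log(alpha)) + logdet_H
  # t' C^-1 t = (t't - t' Phi mu) / sigma2   (Woodbury)
  quad <- (sum(t^2) - sum(t * drop(Phi_active %*% stats$mu))) / sigma2
  ll <- -0.5 * (n * log(2 * pi) + logdet_C + quad)
  if (!is.finite(ll))
    stop("log_marginal_likelihood: non-finite result", call. = FALSE)
  ll
}
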