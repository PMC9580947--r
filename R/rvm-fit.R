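#' RVM fitting configuration
#'
#' Controls the full-batch type-II maximum-likelihood iteration. Defaults
#' give a weakly informative start and a conservative stopping rule.
#'
#' @param alpha_init Initial weight precision for every basis function.
#' @param sigma2_init_fraction Initial noise variance as a fraction of
#'   `var(t)`.
#' @param sigma2_init Absolute initial noise variance; overrides
#'   `sigma2_init_fraction` when given.
#' @param alpha_prune_threshold Basis functions whose precision reaches
#'   this value are removed permanently (alpha effectively infinite).
#'   Must be >= 1e6.
#' @param max_iterations Iteration cap for the re-estimation loop.
#' @param logml_rel_tolerance Stop when the relative change of the log
#'   marginal likelihood falls below this.
#' @param clamp_sigma2_min_fraction Noise-variance floor as a fraction of
#'   `var(t)`, guarding noiseless targets against division by zero.
#' @param include_kernel_intercept Add a bias column to kernel designs.
#' @param center_target Center the targets before fitting and restore the
#'   mean at prediction time.
#' @param update_alpha Set to `FALSE` to freeze all precisions at
#'   `alpha_init` (no pruning happens); the frozen-alpha fit is exactly
#'   penalized least squares.
#' @param noise_update How the noise variance is re-estimated.
#'   `"two_stage"` holds it at its initial value until the precision
#'   iteration first converges, then re-estimates both jointly; `"joint"`
#'   re-estimates from the first iteration; `"fixed"` never re-estimates.
#'   The default `"auto"` resolves to `"fixed"` for over-complete designs
#'   (more basis functions than observations) and `"two_stage"` otherwise:
#'   when the active set can interpolate the targets, the marginal
#'   likelihood is unbounded as `sigma2 -> 0`, and chasing that degenerate
#'   maximum destroys both sparsity and generalization, so the noise level
#'   is kept at its initialized value instead.
#' @param seed Optional integer recorded with the model for provenance.
#' @return An object of class `rvm_config`.
#' @export
rvm_config <- function(alpha_init = 1e-3,
                       sigma2_init_fraction = 0.5,
                       sigma2_init = NULL,
                       alpha_prune_threshold = 1e12,
                       max_iterations = 1000L,
                       logml_rel_tolerance = 1e-6,
                       clamp_sigma2_min_fraction = 1e-10,
                       include_kernel_intercept = FALSE,
                       center_target = TRUE,
                       update_alpha = TRUE,
                       noise_update = c("auto", "two_stage", "joint", "fixed"),
                       seed = NA_integer_) {
  noise_update <- match.arg(noise_update)
  stopifnot(alpha_init > 0, sigma2_init_fraction > 0, sigma2_init_fraction <= 1,
            alpha_prune_threshold >= 1e6, max_iterations >= 1,
            logml_rel_tolerance > 0, clamp_sigma2_min_fraction > 0)
  structure(list(alpha_init = alpha_init,
                 sigma2_init_fraction = sigma2_init_fraction,
                 sigma2_init = sigma2_init,
                 alpha_prune_threshold = alpha_prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 logml_rel_tolerance = logml_rel_tolerance,
                 clamp_sigma2_min_fraction = clamp_sigma2_min_fraction,
                 include_kernel_intercept = isTRUE(include_kernel_intercept),
                 center_target = isTRUE(center_target),
                 update_alpha = isTRUE(update_alpha),
                 noise_update = noise_update,
                 seed = seed),
            class = "rvm_config")
}

.empty_rvm <- function(basis_kind, n, n_basis, target_mean, sigma2, note) {
  structure(list(basis_kind = basis_kind,
                 active = integer(0), weights = numeric(0),
                 alpha = numeric(0), sigma2 = sigma2,
                 target_mean = target_mean,
                 logml_trace = numeric(0), n_iter = 0L, converged = TRUE,
                 n_train = n, n_basis = n_basis, notes = note),
            class = "rvm")
}

#' Fit a relevance vector machine on a prepared design matrix
#'
#' Full-batch re-estimation: starting from uniform precisions, each
#' iteration computes the weight posterior, re-estimates all precisions and
#' the noise variance, permanently removes columns whose precision reaches
#' the pruning threshold, and evaluates the log marginal likelihood. The
#' loop stops when the relative likelihood change drops below
#' `logml_rel_tolerance` or after `max_iterations`.
#'
#' @param Phi Design matrix from [build_design_matrix()] (or any numeric
#'   N x B matrix; the `basis_kind` attribute is carried into the model).
#' @param t Length-N numeric target vector without missing values.
#' @param config An [rvm_config()].
#' @return An object of class `rvm` holding the surviving column indices
#'   (`active`), their posterior mean weights (`weights`), precisions,
#'   noise variance, the centered-target mean, and the per-iteration log
#'   marginal likelihood trace. A target with no signal (or a fit that
#'   prunes every column) yields an empty model that predicts the target
#'   mean; its `notes` field records why.
#' @export
fit_rvm <- function(Phi, t, config = rvm_config()) {
  Phi <- as.matrix(Phi)
  basis_kind <- attr(Phi, "basis_kind")
  if (is.null(basis_kind)) basis_kind <- "linear_basis"
  n <- nrow(Phi); B <- ncol(Phi)
  if (length(t) != n) stop("fit_rvm: length(t) != nrow(Phi)", call. = FALSE)
  if (anyNA(t)) stop("fit_rvm: t contains missing values; filter upstream", call. = FALSE)
  if (n < 2L) stop("fit_rvm: need at least 2 observations", call. = FALSE)

  target_mean <- if (config$center_target) mean(t) else 0
  tc <- t - target_mean
  vt <- stats::var(tc)
  if (vt == 0)
    return(.empty_rvm(basis_kind, n, B, target_mean,
                      max(config$clamp_sigma2_min_fraction, 1e-12),
                      "constant target; no basis retained"))

  sigma2 <- if (!is.null(config$sigma2_init)) config$sigma2_init
            else config$sigma2_init_fraction * vt
  sigma2_min <- config$clamp_sigma2_min_fraction * vt
  prune_at <- config$alpha_prune_threshold

  active <- seq_len(B)
  alpha <- rep(config$alpha_init, B)
  logml_trace <- numeric(0)
  n_active_trace <- integer(0)
  logml_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  ps <- NULL
  noise_update <- config$noise_update
  if (noise_update == "auto")
    noise_update <- if (B > n) "fixed" else "two_stage"
  if (!config$update_alpha && noise_update == "two_stage")
    noise_update <- "joint"
  # under two_stage, stage 1 freezes the noise variance until the precision
  # iteration has converged; stage 2 re-estimates alpha and sigma2 jointly
  stage <- if (noise_update == "two_stage") 1L else 2L
  sigma2_live <- noise_update != "fixed"

  while (iter < config$max_iterations) {
    iter <- iter + 1L
    ps <- .posterior_core(Phi[, active, drop = FALSE], tc, alpha, sigma2)
    logml <- -0.5 * (n * log(2 * pi) + ps$logdet_C + ps$quad)
    if (!is.finite(logml))
      stop("fit_rvm: non-finite log marginal likelihood", call. = FALSE)
    logml_trace <- c(logml_trace, logml)
    n_active_trace <- c(n_active_trace, length(active))

    if (is.finite(logml_prev)) {
      rel <- abs(logml - logml_prev) / (abs(logml_prev) + .Machine$double.eps)
      if (rel < config$logml_rel_tolerance) {
        if (stage == 1L) { stage <- 2L; logml_prev <- -Inf }
        else { converged <- TRUE; break }
      } else logml_prev <- logml
    } else logml_prev <- logml

    if (!config$update_alpha && !sigma2_live) { converged <- TRUE; break }
    upd <- update_hyperparameters(Phi[, active, drop = FALSE], tc,
                                  alpha, sigma2, ps$Sigma_diag, ps$mu,
                                  prune_threshold = prune_at,
                                  sigma2_min = sigma2_min)
    if (config$update_alpha) {
      keep <- upd$alpha < prune_at
      if (!any(keep)) {
        return(.empty_rvm(basis_kind, n, B, target_mean, sigma2,
                          "all basis functions pruned"))
      }
      active <- active[keep]
      alpha <- upd$alpha[keep]
    }
    if (sigma2_live && stage == 2L) sigma2 <- upd$sigma2
  }

  # weights must reflect the final hyperparameters and active set
  ps <- .posterior_core(Phi[, active, drop = FALSE], tc, alpha, sigma2)

  structure(list(basis_kind = basis_kind,
                 active = active, weights = ps$mu,
                 alpha = alpha, sigma2 = sigma2,
                 target_mean = target_mean,
                 logml_trace = logml_trace,
                 n_active_trace = n_active_trace,
                 n_iter = iter, converged = converged,
                 n_train = n, n_basis = B, notes = NULL),
            class = "rvm")
}

#' Fit an RVM from genotypes and a kernel specification
#'
#' High-level interface: builds the design matrix for `spec`, fits the RVM,
#' and attaches everything prediction needs — the kernel specification and,
#' in kernel mode, the genotype rows of the relevance vectors (only those
#' rows; the full training set is not retained).
#'
#' @param X Genotype matrix, N individuals x M markers, coded 0/1.
#' @param t Length-N numeric phenotype vector, no missing values.
#' @param spec A [kernel_spec()]; `"linear_basis"` puts sparsity on markers,
#'   the kernel families put it on training individuals.
#' @param config An [rvm_config()].
#' @return An `rvm` object. In basis mode `relevance_markers(model)` gives
#'   the surviving marker indices; in kernel mode `model$rv_index` gives the
#'   surviving training individuals and `model$rv_inputs` their genotypes.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200 * 12, 1, 0.5), 200, 12)
#' t <- 2 * X[, 3] - 1.5 * X[, 7] + rnorm(200, sd = 0.3)
#' m <- rvm(X, t, kernel_spec("linear_basis"))
#' relevance_markers(m)
#' @export
rvm <- function(X, t, spec = kernel_spec("linear_basis"), config = rvm_config()) {
  X <- as.matrix(X)
  Phi <- build_design_matrix(X, spec,
                             include_kernel_intercept = config$include_kernel_intercept)
  model <- fit_rvm(Phi, t, config)
  model$kernel <- spec
  model$n_features <- ncol(X)
  cm <- attr(Phi, "column_meaning")
  model$column_meaning <- cm[model$active]
  if (model$basis_kind == "kernel") {
    tp <- model$active - as.integer(config$include_kernel_intercept)
    model$rv_index <- tp[model$column_meaning == "training_point"]
    model$rv_inputs <- X[model$rv_index, , drop = FALSE]
  }
  model
}

#' Marker indices retained by a basis RVM
#'
#' @param model An `rvm` fitted in `"linear_basis"` mode.
#' @return Integer vector of surviving marker indices (intercept excluded).
#' @export
relevance_markers <- function(model) {
  stopifnot(inherits(model, "rvm"))
  if (model$basis_kind != "linear_basis")
    stop("relevance_markers: model is kernel-mode; its relevance vectors are ",
         "training individuals, not markers", call. = FALSE)
  act <- model$active
  act[act > 1L] - 1L
}

#' Weights of the retained markers of a basis RVM
#'
#' @param model An `rvm` fitted in `"linear_basis"` mode.
#' @return Named numeric vector of posterior mean weights, names are marker
#'   indices; the intercept weight is dropped.
#' @export
relevance_weights <- function(model) {
  idx <- relevance_markers(model)
  w <- model$weights[model$active > 1L]
  names(w) <- idx
  w
}

#' Predict phenotypes from a fitted RVM
#'
#' Kernel mode sums `w_r * K(x*, x_r)` over the relevance vectors; basis
#' mode evaluates the sparse linear model over the retained markers. Any
#' target centering applied at fit time is inverted.
#'
#' @param object An `rvm` from [rvm()].
#' @param X_new Matrix of new genotypes, Q x M with M as in training.
#' @param ... Unused.
#' @return Numeric vector of Q predictions.
#' @export
predict.rvm <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (!is.null(object$n_features) && ncol(X_new) != object$n_features)
    stop("predict.rvm: X_new has ", ncol(X_new), " columns but the model was ",
         "trained on ", object$n_features, call. = FALSE)
  q <- nrow(X_new)
  if (length(object$active) == 0L) return(rep(object$target_mean, q))

  y <- rep(0, q)
  if (object$basis_kind == "linear_basis") {
    has_int <- object$active == 1L
    if (any(has_int)) y <- y + object$weights[has_int]
    mk <- object$active > 1L
    if (any(mk))
      y <- y + drop(X_new[, object$active[mk] - 1L, drop = FALSE] %*%
                      object$weights[mk])
  } else {
    is_int <- object$column_meaning == "intercept"
    if (any(is_int)) y <- y + object$weights[is_int]
    if (length(object$rv_index))
      y <- y + drop(kernel_matrix(X_new, object$rv_inputs, object$kernel) %*%
                      object$weights[!is_int])
  }
  y + object$target_mean
}

#' @export
print.rvm <- function(x, ...) {
  kind <- if (x$basis_kind == "linear_basis") "linear basis" else
    paste0("kernel (", if (!is.null(x$kernel)) kernel_label(x$kernel) else "?", ")")
  cat("<rvm> ", kind, " model\n", sep = "")
  cat("  training size: ", x$n_train, "; basis functions: ", x$n_basis,
      "; retained: ", length(x$active), "\n", sep = "")
  cat("  sigma2: ", format(x$sigma2, digits = 4),
      "; iterations: ", x$n_iter,
      if (isTRUE(x$converged)) " (converged)" else " (iteration cap)", "\n", sep = "")
  if (!is.null(x$notes)) cat("  note: ", x$notes, "\n", sep = "")
  invisible(x)
}
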