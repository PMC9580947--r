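#' Coefficient of determination on held-out predictions
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the total sum of squares around the
#' mean of the observed values. Can be negative when predictions are worse
#' than the mean.
#'
#' @param y_true Observed values (length >= 2, not constant).
#' @param y_pred Predicted values, same length.
#' @return Scalar R-squared.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("r_squared: length mismatch", call. = FALSE)
  if (length(y_true) < 2L) stop("r_squared: need at least 2 values", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("r_squared: y_true is constant", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Cross-validation configuration
#'
#' @param repeats Number of independent repeats, each with freshly
#'   randomized folds.
#' @param folds Number of folds per repeat.
#' @param seed Integer; repeat r partitions with seed `seed + r`.
#' @param shuffle Randomize fold membership (the standard protocol); with
#'   `FALSE`, folds are contiguous blocks.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(repeats = 10L, folds = 10L, seed = 0L, shuffle = TRUE) {
  repeats <- as.integer(repeats); folds <- as.integer(folds)
  stopifnot(repeats >= 1L, folds >= 2L)
  structure(list(repeats = repeats, folds = folds, seed = as.integer(seed),
                 shuffle = isTRUE(shuffle)),
            class = "cv_config")
}

.fold_assignment <- function(n, folds, seed, shuffle) {
  base <- rep(seq_len(folds), length.out = n)
  if (!shuffle) return(sort(base))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample(base)
}

#' Repeated k-fold cross-validation of an RVM
#'
#' For each repeat, individuals are partitioned into `folds` random folds;
#' an RVM is fitted on each training split and scored by [r_squared()] on
#' the held-out fold. The per-repeat score is the mean over folds; the
#' summary `mean_r2` / `std_r2` are the mean and standard deviation across
#' the repeat means. Deterministic given `cv_cfg$seed`.
#'
#' @param X Genotype matrix, N x M, coded 0/1.
#' @param t Length-N phenotype vector without missing values.
#' @param spec A [kernel_spec()] naming the model to evaluate.
#' @param rvm_cfg An [rvm_config()].
#' @param cv_cfg A [cv_config()].
#' @return An object of class `cv_result` with `per_fold_r2`
#'   (repeats x folds), `per_repeat_mean_r2`, `mean_r2`, `std_r2` and
#'   `model_label`.
#' @export
repeated_kfold_cv <- function(X, t, spec = kernel_spec("linear_basis"),
                              rvm_cfg = rvm_config(), cv_cfg = cv_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(t)) stop("repeated_kfold_cv: t contains missing values; ",
                     "filter upstream", call. = FALSE)
  if (n < cv_cfg$folds)
    stop("repeated_kfold_cv: fewer individuals (", n, ") than folds (",
         cv_cfg$folds, ")", call. = FALSE)
  per_fold <- matrix(NA_real_, cv_cfg$repeats, cv_cfg$folds)
  for (r in seq_len(cv_cfg$repeats)) {
    fold_of <- .fold_assignment(n, cv_cfg$folds, cv_cfg$seed + r, cv_cfg$shuffle)
    for (f in seq_len(cv_cfg$folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      model <- rvm(X[train, , drop = FALSE], t[train], spec = spec,
                   config = rvm_cfg)
      pred <- predict(model, X[test, , drop = FALSE])
      per_fold[r, f] <- r_squared(t[test], pred)
    }
  }
  per_repeat <- rowMeans(per_fold)
  structure(list(per_fold_r2 = per_fold,
                 per_repeat_mean_r2 = per_repeat,
                 mean_r2 = mean(per_repeat),
                 std_r2 = stats::sd(per_repeat),
                 model_label = kernel_label(spec),
                 spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$model_label, ": mean R2 = ",
      format(x$mean_r2, digits = 4), " (std ", format(x$std_r2, digits = 3),
      ") over ", length(x$per_repeat_mean_r2), " repeats x ",
      ncol(x$per_fold_r2), " folds\n", sep = "")
  invisible(x)
}

# simpler families win ties: raw linear basis, then increasingly flexible
# kernels; within gaussian, the smaller bandwidth
.family_complexity <- function(spec) {
  base <- match(spec$family, c("linear_basis", "linear", "polynomial", "gaussian"))
  tie <- if (spec$family == "gaussian") spec$gamma else 0
  c(base, tie)
}

#' Select the best RVM over a set of candidate kernels
#'
#' Runs [repeated_kfold_cv()] for every candidate and returns the one with
#' the highest mean held-out R-squared, along with the full comparison
#' table. Exact ties go to the simpler family (linear basis < linear
#' kernel < polynomial < Gaussian), then to the smaller Gaussian bandwidth.
#'
#' @param X,t,rvm_cfg,cv_cfg As in [repeated_kfold_cv()].
#' @param candidates List of [kernel_spec()] objects (>= 1).
#' @return List with `best` (the winning `kernel_spec`), `best_result` (its
#'   `cv_result`), `results` (all `cv_result`s) and `table` (a data frame
#'   of model label, mean R2, std).
#' @export
select_model <- function(X, t, candidates, rvm_cfg = rvm_config(),
                         cv_cfg = cv_config()) {
  if (!length(candidates)) stop("select_model: no candidates", call. = FALSE)
  results <- lapply(candidates, function(spec)
    repeated_kfold_cv(X, t, spec, rvm_cfg, cv_cfg))
  r2 <- vapply(results, `[[`, numeric(1), "mean_r2")
  comp <- t(vapply(candidates, .family_complexity, numeric(2)))
  best_i <- order(-r2, comp[, 1], comp[, 2])[1]
  tab <- data.frame(model = vapply(results, `[[`, character(1), "model_label"),
                    mean_r2 = r2,
                    std_r2 = vapply(results, `[[`, numeric(1), "std_r2"),
                    stringsAsFactors = FALSE)
  list(best = candidates[[best_i]], best_result = results[[best_i]],
       results = results, table = tab)
}

#' Default candidate set for model selection
#'
#' Linear basis, linear kernel, and a Gaussian kernel for each bandwidth in
#' the default grid — the comparison run per trait.
#'
#' @param gamma_grid Gaussian bandwidths (default [default_gamma_grid()]).
#' @return List of `kernel_spec` objects.
#' @export
default_candidates <- function(gamma_grid = default_gamma_grid()) {
  c(list(kernel_spec("linear_basis"), kernel_spec("linear")),
    lapply(gamma_grid, function(g) kernel_spec("gaussian", gamma = g)))
}

#' Pearson correlation between two vectors
#'
#' Used to relate per-trait prediction accuracies to heritability
#' estimates; thin validation wrapper around [stats::cor()].
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @return Sample Pearson correlation coefficient in [-1, 1].
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("pearson_correlation: length mismatch", call. = FALSE)
  if (length(a) < 3L) stop("pearson_correlation: need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("pearson_correlation: constant input", call. = FALSE)
  stats::cor(a, b, method = "pearson")
}
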