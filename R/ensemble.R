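#' Ensemble configuration for bagged marker ranking
#'
#' @param n_models Number of linear basis RVMs in the ensemble.
#' @param subsample_fraction_range Length-2 interval inside (0, 1); each
#'   model subsamples a fraction of individuals drawn uniformly from this
#'   range, without replacement.
#' @param threshold_fraction Fraction of models that must select a marker
#'   for it to be called influential (default: half the ensemble).
#' @param base_seed Integer; model j uses seed `base_seed + j`, which makes
#'   results independent of execution order and worker count.
#' @param parallel_workers Number of forked workers for model fitting;
#'   `0` or `1` runs serially.
#' @param replacement Draw subsamples with replacement (classic bootstrap)
#'   instead of the default subsampling without replacement.
#' @param max_failure_fraction Proportion of per-model fit errors tolerated
#'   before the ensemble itself fails.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_models = 400L,
                            subsample_fraction_range = c(0.50, 0.60),
                            threshold_fraction = 0.5,
                            base_seed = 0L,
                            parallel_workers = 0L,
                            replacement = FALSE,
                            max_failure_fraction = 0.1) {
  n_models <- as.integer(n_models)
  stopifnot(n_models >= 2L,
            length(subsample_fraction_range) == 2L,
            subsample_fraction_range[1] > 0, subsample_fraction_range[2] < 1,
            subsample_fraction_range[1] <= subsample_fraction_range[2],
            threshold_fraction > 0, threshold_fraction <= 1)
  structure(list(n_models = n_models,
                 subsample_fraction_range = as.numeric(subsample_fraction_range),
                 threshold_fraction = threshold_fraction,
                 base_seed = as.integer(base_seed),
                 parallel_workers = as.integer(parallel_workers),
                 replacement = isTRUE(replacement),
                 max_failure_fraction = max_failure_fraction),
            class = "ensemble_config")
}

#' Draw a deterministic subsample of individuals
#'
#' `floor(fraction * n)` distinct indices drawn uniformly without
#' replacement (or with replacement if requested), using a private RNG
#' stream so the caller's RNG state is untouched.
#'
#' @param n Number of individuals.
#' @param fraction Subsampling fraction in (0, 1).
#' @param rng_seed Integer seed; equal seeds give equal draws.
#' @param replacement Sample with replacement.
#' @return Integer vector of row indices, length `floor(fraction * n)`.
#' @export
subsample_indices <- function(n, fraction, rng_seed, replacement = FALSE) {
  if (fraction <= 0 || fraction >= 1)
    stop("subsample_indices: fraction must be in (0, 1)", call. = FALSE)
  size <- floor(fraction * n)
  if (size < 2L)
    stop("subsample_indices: subsample of ", size, " individuals is too small",
         call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng_seed)
  sort(sample.int(n, size, replace = replacement))
}

.fit_one_bag <- function(j, X, t, cfg, rvm_cfg) {
  seed_j <- cfg$base_seed + j
  # the per-model fraction comes from the same private stream as the draw
  old <- globalenv()$.Random.seed
  set.seed(seed_j)
  frac <- stats::runif(1, cfg$subsample_fraction_range[1],
                       cfg$subsample_fraction_range[2])
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  idx <- subsample_indices(nrow(X), frac, seed_j, replacement = cfg$replacement)
  model <- rvm(X[idx, , drop = FALSE], t[idx],
               spec = kernel_spec("linear_basis"), config = rvm_cfg)
  model$bag_seed <- seed_j
  model$bag_indices <- idx
  model
}

#' Fit a bagged ensemble of linear basis RVMs
#'
#' Trains `n_models` basis RVMs, each on a random 50--60% subsample of
#' individuals (by default). Per-model seeding (`base_seed + j`) makes the
#' ensemble reproducible and identical whether it runs serially or over
#' forked workers.
#'
#' @param X Genotype matrix, N x M, coded 0/1.
#' @param t Length-N phenotype vector without missing values (align and
#'   filter upstream, e.g. with [align_and_filter()]).
#' @param cfg An [ensemble_config()].
#' @param rvm_cfg An [rvm_config()] applied to every member model.
#' @return An object of class `rvm_ensemble`: a list of fitted `rvm`
#'   models with the configuration and any per-model failures attached.
#'   Individual fit errors become warnings; the ensemble fails only when
#'   more than `max_failure_fraction` of the models error.
#' @export
fit_ensemble <- function(X, t, cfg = ensemble_config(), rvm_cfg = rvm_config()) {
  X <- as.matrix(X)
  if (anyNA(t)) stop("fit_ensemble: t contains missing values", call. = FALSE)
  run_one <- function(j) {
    tryCatch(.fit_one_bag(j, X, t, cfg, rvm_cfg),
             error = function(e) structure(list(seed = cfg$base_seed + j,
                                                message = conditionMessage(e)),
                                           class = "rvm_bag_failure"))
  }
  jobs <- seq_len(cfg$n_models)
  models <- if (cfg$parallel_workers > 1L) {
    parallel::mclapply(jobs, run_one, mc.cores = cfg$parallel_workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(jobs, run_one)
  }
  failed <- vapply(models, inherits, logical(1), what = "rvm_bag_failure")
  if (any(failed)) {
    msgs <- vapply(models[failed], function(f)
      sprintf("seed %d: %s", f$seed, f$message), character(1))
    if (mean(failed) > cfg$max_failure_fraction)
      stop("fit_ensemble: ", sum(failed), "/", cfg$n_models,
           " member fits failed:\n  ", paste(msgs, collapse = "\n  "),
           call. = FALSE)
    warning("fit_ensemble: ", sum(failed), " member fit(s) failed and were ",
            "dropped:\n  ", paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  structure(list(models = models[!failed],
                 n_requested = cfg$n_models,
                 n_failed = sum(failed),
                 n_markers = ncol(X),
                 config = cfg),
            class = "rvm_ensemble")
}

#' Rank markers by how often an ensemble selects them
#'
#' Aggregates the relevance vectors of an ensemble of basis RVMs. A
#' marker's count is the number of member models that retained it
#' (intercepts never participate); its mean weight is the average of its
#' posterior weights over those models, and its sign is the sign of that
#' mean. Markers are ordered by count (descending), then `|mean_weight|`
#' (descending), then marker index (ascending) — a deterministic total
#' order. Markers never selected are reported as unranked.
#'
#' @param ensemble An `rvm_ensemble` from [fit_ensemble()], or a plain list
#'   of basis-mode `rvm` models.
#' @param n_markers Total number of markers (required when a plain list is
#'   given).
#' @return An object of class `marker_ranking`: a data frame with columns
#'   `marker` (1-based index), `count`, `rank_fraction`, `mean_weight`,
#'   `sign` (`"+"`, `"-"` or `"0"`), and `rank_order`, one row per ranked
#'   marker; attributes `n_models_run`, `n_markers` and `unranked` (the
#'   zero-count marker indices).
#' @export
rank_markers <- function(ensemble, n_markers = NULL) {
  if (inherits(ensemble, "rvm_ensemble")) {
    models <- ensemble$models
    n_markers <- ensemble$n_markers
  } else {
    models <- ensemble
    if (is.null(n_markers))
      stop("rank_markers: n_markers is required for a plain model list", call. = FALSE)
  }
  for (m in models)
    if (!inherits(m, "rvm") || m$basis_kind != "linear_basis")
      stop("rank_markers: every model must be a basis-mode rvm", call. = FALSE)

  count <- integer(n_markers)
  wsum <- numeric(n_markers)
  for (m in models) {
    idx <- relevance_markers(m)
    if (!length(idx)) next
    w <- relevance_weights(m)
    count[idx] <- count[idx] + 1L
    wsum[idx] <- wsum[idx] + w
  }
  n_run <- length(models)
  ranked <- which(count > 0L)
  mean_weight <- wsum[ranked] / count[ranked]
  ord <- order(-count[ranked], -abs(mean_weight), ranked)
  ranked <- ranked[ord]
  mean_weight <- mean_weight[ord]
  out <- data.frame(marker = ranked,
                    count = count[ranked],
                    rank_fraction = count[ranked] / n_run,
                    mean_weight = mean_weight,
                    sign = ifelse(mean_weight > 0, "+",
                                  ifelse(mean_weight < 0, "-", "0")),
                    rank_order = seq_along(ranked),
                    stringsAsFactors = FALSE)
  structure(out,
            n_models_run = n_run,
            n_markers = n_markers,
            unranked = setdiff(seq_len(n_markers), ranked),
            class = c("marker_ranking", "data.frame"))
}

#' Influential markers at a selection-frequency threshold
#'
#' The most influential markers are those chosen as relevance vectors by at
#' least `threshold_fraction` of the ensemble (default: half of the
#' models), each reported with its sign and mean weight.
#'
#' @param ranking A `marker_ranking` from [rank_markers()].
#' @param threshold_fraction Minimum `rank_fraction` in (0, 1].
#' @return The subset of the ranking meeting the threshold, order
#'   inherited.
#' @export
influential_markers <- function(ranking, threshold_fraction = 0.5) {
  stopifnot(inherits(ranking, "marker_ranking"),
            threshold_fraction > 0, threshold_fraction <= 1)
  out <- ranking[ranking$rank_fraction >= threshold_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k markers of a ranking
#'
#' @param ranking A `marker_ranking`.
#' @param k Number of markers to return; if fewer markers were ever
#'   selected, all ranked markers are returned with a warning.
#' @return The first `k` rows of the deterministic ranking order.
#' @export
top_k_markers <- function(ranking, k) {
  stopifnot(inherits(ranking, "marker_ranking"), k >= 1)
  if (k > nrow(ranking)) {
    warning("top_k_markers: only ", nrow(ranking), " markers were ranked; ",
            "returning all of them", call. = FALSE)
    k <- nrow(ranking)
  }
  out <- ranking[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.marker_ranking <- function(x, n = 10L, ...) {
  cat("<marker_ranking> ", nrow(x), " of ", attr(x, "n_markers"),
      " markers ranked by ", attr(x, "n_models_run"), " models\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}
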