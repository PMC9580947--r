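#' Simulation configuration for a biparental-cross fixture
#'
#' Emulates the shape of a haploid biparental cross: binary genotypes with
#' local linkage correlation, additive marker effects of both signs,
#' optional pairwise epistasis, and Gaussian noise calibrated to a target
#' narrow-sense heritability.
#'
#' @param n_individuals Number of segregants (rows).
#' @param n_markers Number of biallelic markers (columns).
#' @param allele_freq Probability of the "1" parental allele (0.5 in a
#'   balanced cross).
#' @param ld_rho Probability that a marker copies its left neighbour —
#'   a first-order linkage chain; 0 gives independent markers.
#' @param k_causal Number of causal markers.
#' @param effect_distribution `"fixed"`: magnitudes `effect_size` with
#'   alternating signs (half trait-increasing, half trait-decreasing);
#'   `"normal"`: effects drawn from N(0, effect_size^2).
#' @param effect_size Magnitude (fixed) or standard deviation (normal) of
#'   the causal effects, in trait units per allele.
#' @param h2 Target narrow-sense heritability: the noise variance is set so
#'   that additive variance over total variance equals `h2` in expectation.
#'   `h2 = 1` gives a noiseless trait, `h2 = 0` a pure-noise trait.
#' @param epistatic_pairs Optional data frame / matrix with columns
#'   `(i, j, effect)`: each row adds `effect * x_i * x_j` to the genetic
#'   value. Epistatic variance counts toward total but not additive
#'   variance, so realized broad-sense exceeds narrow-sense heritability.
#' @param n_chromosomes Markers receive synthetic IDs `"chr{c}:{pos}"`
#'   spread evenly over this many chromosomes.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 400L, n_markers = 800L,
                       allele_freq = 0.5, ld_rho = 0.9,
                       k_causal = 10L,
                       effect_distribution = c("fixed", "normal"),
                       effect_size = 1,
                       h2 = 0.5,
                       epistatic_pairs = NULL,
                       n_chromosomes = 16L,
                       seed = 1L) {
  effect_distribution <- match.arg(effect_distribution)
  stopifnot(n_individuals >= 2, n_markers >= 1,
            allele_freq > 0, allele_freq < 1,
            ld_rho >= 0, ld_rho < 1,
            k_causal >= 0, k_causal <= n_markers,
            h2 >= 0, h2 <= 1, effect_size > 0, n_chromosomes >= 1)
  if (!is.null(epistatic_pairs)) {
    epistatic_pairs <- as.data.frame(epistatic_pairs)
    colnames(epistatic_pairs) <- c("i", "j", "effect")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 allele_freq = allele_freq, ld_rho = ld_rho,
                 k_causal = as.integer(k_causal),
                 effect_distribution = effect_distribution,
                 effect_size = effect_size, h2 = h2,
                 epistatic_pairs = epistatic_pairs,
                 n_chromosomes = as.integer(n_chromosomes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Synthetic marker IDs of the form "chr{c}:{pos}"
#'
#' @param cfg A [sim_config()].
#' @return Character vector of `n_markers` IDs, positions increasing within
#'   each chromosome at a 5 kb spacing.
#' @export
sim_marker_ids <- function(cfg) {
  m <- cfg$n_markers
  chrom <- rep(seq_len(cfg$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) 5000L * seq_along(ix)),
                use.names = FALSE)
  sprintf("chr%d:%d", chrom, pos)
}

#' Simulate binary genotypes with local linkage
#'
#' The first marker is Bernoulli(`allele_freq`) per individual; each later
#' marker copies its left neighbour with probability `ld_rho` and is
#' otherwise drawn fresh — a first-order chain producing geometrically
#' decaying linkage correlation along the genome.
#'
#' @param cfg A [sim_config()].
#' @return N x M matrix of 0/1 genotypes with marker IDs as column names;
#'   deterministic given `cfg$seed`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed)
  n <- cfg$n_individuals; m <- cfg$n_markers
  X <- matrix(0L, n, m)
  chrom <- sort(rep(seq_len(cfg$n_chromosomes), length.out = m))
  X[, 1] <- stats::rbinom(n, 1L, cfg$allele_freq)
  if (m > 1L) for (j in 2:m) {
    fresh <- stats::rbinom(n, 1L, cfg$allele_freq)
    if (chrom[j] != chrom[j - 1L]) { # chromosomes segregate independently
      X[, j] <- fresh
    } else {
      copy <- stats::runif(n) < cfg$ld_rho
      X[, j] <- ifelse(copy, X[, j - 1L], fresh)
    }
  }
  colnames(X) <- sim_marker_ids(cfg)
  rownames(X) <- sprintf("seg%04d", seq_len(n))
  X
}

#' Simulate a phenotype with known causal structure
#'
#' Draws `k_causal` causal markers, assigns signed additive effects, adds
#' any configured epistatic products, and adds Gaussian noise whose
#' variance is chosen so that the additive fraction of total variance
#' equals the target narrow-sense heritability in expectation. The
#' realized heritability (sample additive variance over sample phenotype
#' variance) is reported in the ground truth.
#'
#' @param X Genotype matrix from [simulate_genotypes()].
#' @param cfg The same [sim_config()].
#' @return List with `t` (length-N phenotype) and `truth`, an object of
#'   class `sim_truth`: `causal_indices`, `effects` (signed, aligned with
#'   `causal_indices`), `noise_variance`, `realized_h2`, and
#'   `realized_broad_h2` (genetic variance fraction including epistasis).
#' @export
simulate_phenotype <- function(X, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  X <- as.matrix(X)
  if (nrow(X) != cfg$n_individuals || ncol(X) != cfg$n_markers)
    stop("simulate_phenotype: X does not match cfg dimensions", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed + 1L)
  n <- nrow(X); k <- cfg$k_causal

  causal <- if (k > 0) sort(sample.int(cfg$n_markers, k)) else integer(0)
  effects <- if (k == 0) numeric(0)
    else if (cfg$effect_distribution == "fixed")
      cfg$effect_size * rep_len(c(1, -1), k)
    else stats::rnorm(k, 0, cfg$effect_size)

  g_add <- if (k > 0) drop(X[, causal, drop = FALSE] %*% effects) else rep(0, n)
  g_epi <- rep(0, n)
  if (!is.null(cfg$epistatic_pairs) && nrow(cfg$epistatic_pairs)) {
    for (r in seq_len(nrow(cfg$epistatic_pairs))) {
      p <- cfg$epistatic_pairs[r, ]
      g_epi <- g_epi + p$effect * X[, p$i] * X[, p$j]
    }
  }
  g <- g_add + g_epi

  var_add <- stats::var(g_add)
  var_epi <- stats::var(g_epi)
  if (cfg$h2 == 0 || var_add == 0) {
    # pure-noise trait: genetic values contribute nothing
    g_add <- g_epi <- g <- rep(0, n)
    sigma2_eps <- 1
  } else if (cfg$h2 == 1) {
    sigma2_eps <- 0
  } else {
    sigma2_eps <- max(var_add / cfg$h2 - var_add - var_epi, 0)
  }
  eps <- if (sigma2_eps > 0) stats::rnorm(n, 0, sqrt(sigma2_eps)) else rep(0, n)
  t <- g + eps

  vt <- stats::var(t)
  truth <- structure(list(causal_indices = causal,
                          effects = effects,
                          noise_variance = sigma2_eps,
                          realized_h2 = if (vt > 0) stats::var(g_add) / vt else 0,
                          realized_broad_h2 = if (vt > 0) stats::var(g) / vt else 0),
                     class = "sim_truth")
  list(t = t, truth = truth)
}

#' Simulate a complete genotype/phenotype dataset
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotype()].
#'
#' @param cfg A [sim_config()].
#' @return List with `X`, `t`, `truth`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  X <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(X, cfg)
  list(X = X, t = ph$t, truth = ph$truth)
}

#' Recovery metrics of a ranking against simulated truth
#'
#' @param truth A `sim_truth` from [simulate_phenotype()].
#' @param ranking A `marker_ranking` from [rank_markers()].
#' @param k Depth of the ranking to evaluate.
#' @return List with `precision_at_k` (fraction of the top-k that are
#'   causal), `recall_at_k` (fraction of causal markers in the top-k), and
#'   `sign_agreement` (fraction of recovered causal markers whose ranking
#'   sign matches the simulated effect sign; `NaN` when none recovered).
#' @export
recovery_metrics <- function(truth, ranking, k) {
  stopifnot(inherits(truth, "sim_truth"), k >= 1)
  top <- suppressWarnings(top_k_markers(ranking, k))
  hit <- top$marker %in% truth$causal_indices
  recovered <- top$marker[hit]
  sign_true <- sign(truth$effects[match(recovered, truth$causal_indices)])
  sign_rank <- ifelse(top$sign[hit] == "+", 1, ifelse(top$sign[hit] == "-", -1, 0))
  list(precision_at_k = sum(hit) / k,
       recall_at_k = if (length(truth$causal_indices))
         sum(hit) / length(truth$causal_indices) else NaN,
       sign_agreement = if (length(recovered))
         mean(sign_rank == sign_true) else NaN)
}
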