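---
title: "Sparse Bayesian regression for genomic prediction and marker ranking"
author: "rvmsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse Bayesian regression for genomic prediction and marker ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvmsel)
```

## The model

`rvmsel` predicts a quantitative phenotype $t$ from genome-wide biallelic
markers coded 0/1 by parental origin, and ranks markers by their relevance
to the trait. The workhorse is the relevance vector machine (RVM), a
sparse Bayesian linear model

$$y(\mathbf{x}; \mathbf{w}) = \sum_{m} w_m\, \rho_m(\mathbf{x}),
\qquad t_i = y(\mathbf{x}_i) + \epsilon_i,\quad
\epsilon_i \sim \mathcal{N}(0, \sigma^2),$$

with an independent zero-mean Gaussian prior on each weight,
$w_m \sim \mathcal{N}(0, \alpha_m^{-1})$. The per-weight precisions
$\alpha_m$ are the automatic-relevance-determination mechanism: maximizing
the marginal likelihood $p(\mathbf{t} \mid \boldsymbol\alpha, \sigma^2)$
drives the precision of an uninformative basis function to infinity, which
pins its weight to zero and removes it. The surviving basis functions are
the relevance vectors (RVs).

Two parameterizations of $\rho$ are supported and they differ in *what*
becomes sparse:

* **Kernel RVM** — one basis function per training individual,
  $\rho_m(\mathbf{x}) = K(\mathbf{x}, \mathbf{x}_m)$, with linear,
  polynomial $(\mathbf{x}\cdot\mathbf{x}' + c)^d$, or Gaussian
  $\exp(-\gamma\lVert\mathbf{x}-\mathbf{x}'\rVert^2)$ kernels. Sparsity
  selects representative individuals; this is the predictive workhorse.
* **Linear basis RVM** — one basis function per marker plus an intercept
  column, so the design matrix is the $N \times (M{+}1)$ genotype matrix
  itself. Sparsity now falls on markers: the fit is simultaneously a
  predictor and an embedded marker-selection method, and each retained
  marker carries a signed weight (trait-increasing or trait-decreasing).

Fitting iterates the standard type-II maximum-likelihood recursions: the
weight posterior $\Sigma = (\sigma^{-2}\Phi^\top\Phi + A)^{-1}$,
$\mu = \sigma^{-2}\Sigma\Phi^\top\mathbf{t}$ with $A =
\mathrm{diag}(\alpha)$; the precision update $\alpha_m \leftarrow
(1-\alpha_m\Sigma_{mm})/\mu_m^2$; and the noise update $\sigma^2
\leftarrow \lVert\mathbf{t}-\Phi\mu\rVert^2 / (N - \sum_m
(1-\alpha_m\Sigma_{mm}))$. The noise recursion is implemented with the
*squared* residual norm, which the standard derivation requires (some
presentations typeset the norm without its exponent). A basis function is
pruned permanently once $\alpha \ge 10^{12}$, and the loop stops when the
relative change of the log marginal likelihood falls below $10^{-6}$ or
after 1000 iterations. This is the full-batch variant of the algorithm;
the fast sequential (greedy basis-addition) variant is deliberately out of
scope.

## Numerical choices

**Linear algebra.** The active system $H = A + \sigma^{-2}
\Phi_a^\top\Phi_a$ is factorized by Cholesky, retried once with diagonal
jitter $10^{-10}\,\mathrm{tr}(H)/k$, and the log marginal likelihood is
evaluated through the determinant/inversion identities on the $k \times k$
system — the $N \times N$ covariance $C = \sigma^2 I + \Phi A^{-1}
\Phi^\top$ is never formed when $N \gg k$. While the active set is larger
than $N$ (the early iterations of a basis fit with $M \ge N$), the
identities are applied in the opposite direction and the $N \times N$ dual
system is factorized instead, which brings the per-iteration cost from
$O(k^3)$ down to $O(N^2 k)$. Both paths agree to rounding error; unit
tests pin them against dense-inverse oracles.

**Noise schedule.** On an over-complete design (more columns than
observations, i.e. a basis RVM with $M \ge N$) the marginal likelihood is
unbounded as $\sigma^2 \to 0$: as long as the active set can interpolate
the targets, re-estimating the noise every iteration collapses
$\sigma^2$ to its floor, after which nothing is pruned and the fit
memorizes noise. This is a property of the batch algorithm, not of an
implementation (scikit-learn's batch ARD regression exhibits the same
collapse on the same inputs). The default schedule `noise_update =
"auto"` therefore:

* keeps $\sigma^2$ fixed at its initialized value for over-complete
  designs, and
* for identifiable designs ($B \le N$) runs a two-stage schedule —
  precisions to convergence at fixed noise, then joint re-estimation —
  which keeps the Eq-(9)-style noise update active without handing it the
  interpolating basin.

**Initialization.** All precisions start at $\alpha_{\text{init}} =
10^{-3}$ (converged solutions are insensitive to this over several orders
of magnitude; tested). The noise starts at $\sigma^2 = 0.5\,
\mathrm{var}(t)$: for a trait with narrow-sense heritability around 0.5 —
the median for the yeast-cross growth traits this package is aimed at —
half the phenotypic variance is environmental, so this is the natural
a-priori noise level, and under the fixed-noise schedule the
initialization *is* the working noise level. Targets are centered before
fitting (the mean is restored at prediction), which keeps the basis
intercept near zero and makes $\alpha/\sigma^2$ scales comparable across
traits. Genotypes enter kernels as raw 0/1 values without centering or
scaling. A floor of $10^{-10}\,\mathrm{var}(t)$ on $\sigma^2$ guards
noiseless targets; a constant target short-circuits to an empty model that
predicts the mean.

**Degenerate inputs.** If every column is pruned the fit returns an empty
model (predicting the target mean) rather than an error, with a note on
the model object. The kernel design has no bias column by default,
matching the kernel expansion $\rho(\mathbf{x}_i) = (K(\mathbf{x}_i,
\mathbf{x}_1), \ldots)$; `include_kernel_intercept = TRUE` opts in.

## Marker ranking by a bagged ensemble

A single basis RVM is a noisy selector, so ranking uses bagging: 400
linear basis RVMs by default, each trained on a random 50–60% subsample
of individuals drawn *without* replacement (the classic
with-replacement bootstrap is available behind `replacement = TRUE`).
Each model's per-subsample fraction is drawn uniformly from the range.
Model $j$ is seeded `base_seed + j`, so the ensemble is reproducible and
independent of execution order — running on one worker or many forked
workers gives byte-identical rankings.

Aggregation counts, for every marker, the number of member models that
retained it as an RV (intercepts never participate). Markers are ordered
by count, ties broken by the magnitude of the mean retained weight, then
by marker index — a deterministic total order. Markers never selected are
reported as unranked: the ensemble's way of saying they show no effect at
all. The *influential* set is the markers chosen by at least a threshold
fraction of the ensemble (default one half), each with the sign of its
mean weight — the signed effect is what distinguishes growth-increasing
from growth-decreasing alleles. The ensemble is used only for ranking,
not for aggregated prediction.

## Evaluation protocol

Prediction accuracy is the coefficient of determination on held-out data,
$R^2 = 1 - \mathrm{SS}_{\text{res}}/\mathrm{SS}_{\text{tot}}$ (not the
squared correlation; the two differ under miscalibrated predictions, and
the sums-of-squares form is the stricter, more common reading).
`repeated_kfold_cv()` runs 10 repeats of 10-fold cross-validation by
default, each repeat with a freshly seeded random partition; $R^2$ is
computed per fold, averaged within repeat, and the reported spread is the
standard deviation across the 10 repeat means. Individuals with a missing
value for the trait under study are dropped before partitioning.
`select_model()` compares a candidate set — by default the linear basis,
the linear kernel, and Gaussian kernels with $\gamma \in \{1, 2, 3\}
\times 10^{-4}$ — and breaks exact ties toward the simpler family.
`pearson_correlation()` supports the downstream question of how accuracy
tracks heritability across traits.

## What the synthetic generator emulates

`sim_config()` produces fixtures shaped like a haploid biparental cross:

* **Genotypes** are 0/1 by parental origin, `allele_freq = 0.5` as in a
  balanced cross. Linkage is a first-order chain: each marker copies its
  left neighbour with probability `ld_rho`, resetting at chromosome
  boundaries (16 chromosomes by default). The default `ld_rho = 0.9`
  reflects a dense marker map: with on the order of 50 markers per
  chromosome and roughly five crossovers per chromosome per meiosis, the
  chance that adjacent markers share parental origin is about 0.9. This
  one-parameter chain reproduces the feature that matters for ranking —
  clusters of correlated markers tagging a shared locus — but not
  recombination-map heterogeneity, genotyping error, or population
  structure.
* **Phenotypes** are additive effects at `k_causal` markers (default 10,
  the order of detected QTL per trait in such crosses), either fixed
  magnitudes with alternating signs (default: a controlled fixture where
  signal strength is set by `k_causal` and `h2` alone) or Gaussian
  effects, plus optional pairwise epistatic products, plus Gaussian noise.
  The noise variance is chosen so that the additive fraction of total
  variance equals the target narrow-sense heritability `h2` *in
  expectation*; the realized value is reported in the ground truth rather
  than enforced exactly, which would distort the noise distribution.
  With epistatic pairs configured, broad-sense (total genetic)
  heritability exceeds the narrow-sense value, mirroring real crosses.

Because the generator is additive-by-construction (unless epistasis is
requested) and its linkage is homogeneous, passing tests demonstrate
correct algorithmic behavior under controlled conditions — they do not
certify accuracy levels on real crosses, where effect-size distributions,
map structure, and non-genetic covariates differ.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
full suite completes in a few minutes on one CPU: marker recovery uses 300
individuals × 1000 markers with a 100-model ensemble; cross-validated
prediction uses 400 × 800 with 5 repeats of 5-fold CV over five candidate
models; oracle checks use dozens of small random instances. The same code
paths scale to a full cross (a thousand segregants, ~10⁴ markers) per
trait; the ensemble parallelizes over forked workers.

## Known limitations

* The batch RVM retains more markers than the greedy sequential variant
  would. Under tight linkage it keeps several tagging markers per causal
  locus (typically 7–13% of markers on the default synthetic scenario
  rather than a handful), because LD-mates genuinely carry signal and the
  batch fixed point has no mechanism to keep exactly one representative
  per block. Ranking quality is unaffected — the ensemble counts
  concentrate on causal loci — but single-fit marker lists should be read
  as tagging sets, not minimal causal sets.
* With `noise_update = "auto"` on over-complete designs, $\sigma^2$ is a
  fixed assumption rather than an estimate; the reported `sigma2` of such
  models should not be interpreted as a noise-variance estimate.
* Kernel-RVM accuracy with the default $\gamma$ grid depends on the scale
  of squared distances between genotype rows, which grows with the number
  of markers; for marker counts far from the motivating dataset's, the
  grid should be rescaled (`default_gamma_grid()` is user-overridable
  everywhere it is consumed).
* Heritability is an input to the simulator, not something the package
  estimates from data.
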