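test_that("subsample_indices draws distinct, reproducible, in-range indices", {
  idx <- subsample_indices(100, 0.5, rng_seed = 7)
  expect_length(idx, 50)
  expect_false(anyDuplicated(idx) > 0)
  expect_true(all(idx >= 1 & idx <= 100))
  expect_identical(idx, subsample_indices(100, 0.5, rng_seed = 7))
  expect_false(identical(idx, subsample_indices(100, 0.5, rng_seed = 8)))
  expect_error(subsample_indices(3, 0.5, 1), "too small")
  expect_error(subsample_indices(100, 1.2, 1), "fraction")
})

test_that("subsampling is uniform over individuals", {
  draws <- 2000
  hits <- integer(10)
  for (s in seq_len(draws))
    hits[subsample_indices(10, 0.5, rng_seed = s)] <-
      hits[subsample_indices(10, 0.5, rng_seed = s)] + 1L
  # each index should appear in about half the draws; 99.9% binomial band
  band <- 3.3 * sqrt(draws * 0.25)
  expect_true(all(abs(hits - draws / 2) < band))
})

test_that("ranking arithmetic matches hand computation", {
  models <- list(fake_basis_model(3, 1), fake_basis_model(3, 2),
                 fake_basis_model(c(3, 8), c(3, -2)),
                 fake_basis_model(3, 2), fake_basis_model(c(3, 5), c(2, -1)))
  rk <- rank_markers(models, n_markers = 10)
  row3 <- rk[rk$marker == 3, ]
  expect_equal(row3$count, 5L)
  expect_equal(row3$mean_weight, 2)
  expect_equal(row3$sign, "+")
  expect_equal(rk$marker[1], 3)              # highest count first
  expect_setdiff <- setdiff(1:10, c(3, 5, 8))
  expect_identical(attr(rk, "unranked"), expect_setdiff)
  # negative-effect markers keep their sign
  expect_equal(rk[rk$marker == 8, ]$sign, "-")
})

test_that("ranking order is deterministic: count, then |weight|, then index", {
  models <- list(fake_basis_model(c(1, 2, 4), c(0.5, -3, 0.5)),
                 fake_basis_model(c(1, 2), c(0.5, -3)))
  rk <- rank_markers(models, n_markers = 5)
  expect_identical(rk$marker, c(2L, 1L, 4L))  # 2: count 2 |w| 3; 1: count 2; 4: count 1
  expect_identical(rk$rank_order, 1:3)
})

test_that("counts equal a brute-force tally over fitted models", {
  cfg <- sim_config(n_individuals = 120, n_markers = 60, k_causal = 4,
                    h2 = 0.7, ld_rho = 0.2, seed = 12)
  d <- simulate_dataset(cfg)
  ens <- fit_ensemble(d$X, d$t, ensemble_config(n_models = 6, base_seed = 5))
  rk <- rank_markers(ens)
  tally <- integer(60)
  for (m in ens$models) {
    sel <- relevance_markers(m)
    tally[sel] <- tally[sel] + 1L
  }
  expect_identical(rk$count, tally[rk$marker])
  expect_true(all(tally[attr(rk, "unranked")] == 0L))
  expect_equal(rk$rank_fraction, rk$count / 6)
})

test_that("each bag uses between 50% and 60% of individuals", {
  X <- rand_geno(100, 20, seed = 13)
  set.seed(13)
  t <- drop(X[, 1:2] %*% c(2, -2)) + rnorm(100, sd = 0.4)
  ens <- fit_ensemble(X, t, ensemble_config(n_models = 3, base_seed = 1))
  sizes <- vapply(ens$models, function(m) length(m$bag_indices), integer(1))
  expect_true(all(sizes >= 50 & sizes <= 60))
  expect_length(ens$models, 3)
})

test_that("a zero trait gives an ensemble with no ranked markers", {
  X <- rand_geno(60, 15, seed = 14)
  ens <- fit_ensemble(X, rep(0, 60), ensemble_config(n_models = 3, base_seed = 2))
  rk <- rank_markers(ens)
  expect_equal(nrow(rk), 0)
  expect_length(attr(rk, "unranked"), 15)
})

test_that("worker count does not change the ranking", {
  cfg <- sim_config(n_individuals = 100, n_markers = 50, k_causal = 3,
                    h2 = 0.7, ld_rho = 0.2, seed = 15)
  d <- simulate_dataset(cfg)
  r1 <- rank_markers(fit_ensemble(d$X, d$t,
          ensemble_config(n_models = 6, base_seed = 9, parallel_workers = 1)))
  r2 <- rank_markers(fit_ensemble(d$X, d$t,
          ensemble_config(n_models = 6, base_seed = 9, parallel_workers = 2)))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("influential markers respect the half-of-ensemble rule", {
  models <- c(replicate(10, fake_basis_model(1, 1), simplify = FALSE),
              replicate(5, fake_basis_model(2, -1), simplify = FALSE),
              replicate(4, fake_basis_model(7, 1), simplify = FALSE))
  # marker 1 in 19? no: marker 1 in first 10 models only
  rk <- rank_markers(models, n_markers = 8)
  infl <- influential_markers(rk, 0.5)
  expect_identical(infl$marker, 1L)           # 10/19 >= 0.5
  expect_identical(influential_markers(rk, 1.0)$marker, integer(0))
  # threshold monotonicity
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    nrow(influential_markers(rk, th)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("top_k returns the leading markers and warns when k is too large", {
  models <- list(fake_basis_model(c(2, 4), c(1, 0.5)),
                 fake_basis_model(2, 1))
  rk <- rank_markers(models, n_markers = 6)
  expect_identical(top_k_markers(rk, 1)$marker, 2L)
  expect_identical(top_k_markers(rk, 2)$marker, c(2L, 4L))
  expect_warning(all_r <- top_k_markers(rk, 5), "only")
  expect_equal(nrow(all_r), 2)
  # sort oracle: top-k member set equals brute-force ordering of tuples
  ord <- order(-rk$count, -abs(rk$mean_weight), rk$marker)
  expect_identical(top_k_markers(rk, 2)$marker, rk$marker[ord][1:2])
})

test_that("mixed-sign causal effects are recovered with matching signs", {
  cfg <- sim_config(n_individuals = 200, n_markers = 300, k_causal = 6,
                    h2 = 0.8, ld_rho = 0.2, seed = 21,
                    effect_distribution = "fixed")
  d <- simulate_dataset(cfg)
  expect_setequal(unique(sign(d$truth$effects)), c(-1, 1))
  ens <- fit_ensemble(d$X, d$t, ensemble_config(n_models = 30, base_seed = 3))
  rk <- rank_markers(ens)
  rec <- recovery_metrics(d$truth, rk, 10)
  expect_gte(rec$recall_at_k, 0.8)
  expect_gte(rec$sign_agreement, 0.9)
  top <- top_k_markers(rk, 10)
  hit <- top$marker %in% d$truth$causal_indices
  expect_true(any(top$sign[hit] == "+") && any(top$sign[hit] == "-"))
})
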