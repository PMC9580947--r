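test_that("r_squared follows the sums-of-squares definition", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  set.seed(1)
  yt <- rnorm(40); yp <- yt + rnorm(40, sd = 0.5)
  oracle <- 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2)
  expect_equal(r_squared(yt, yp), oracle, tolerance = 1e-12)
  expect_error(r_squared(rep(1, 5), rnorm(5)), "constant")
  expect_error(r_squared(1:4, 1:5), "length")
})

test_that("pearson_correlation matches the covariance/variance oracle", {
  a <- c(0.2, 0.5, 0.9, 0.4)
  expect_equal(pearson_correlation(a, a), 1)
  expect_equal(pearson_correlation(a, -a), -1)
  set.seed(2)
  x <- rnorm(25); y <- 0.3 * x + rnorm(25)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), oracle, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("cross-validation folds partition the individuals every repeat", {
  n <- 37; folds <- 5
  for (r in 1:3) {
    fa <- rvmsel:::.fold_assignment(n, folds, seed = r, shuffle = TRUE)
    expect_length(fa, n)
    expect_setequal(unique(fa), 1:folds)
    # balanced to within one individual
    expect_lte(diff(range(table(fa))), 1)
  }
})

test_that("repeated CV is deterministic and near-perfect on a noiseless trait", {
  X <- rand_geno(80, 12, seed = 30)
  t <- drop(X[, c(2, 9)] %*% c(2, -1))
  cvc <- cv_config(repeats = 2, folds = 4, seed = 5)
  res <- repeated_kfold_cv(X, t, kernel_spec("linear_basis"), cv_cfg = cvc)
  expect_gt(res$mean_r2, 0.99)
  expect_equal(dim(res$per_fold_r2), c(2, 4))
  expect_equal(res$mean_r2, mean(res$per_repeat_mean_r2))
  res2 <- repeated_kfold_cv(X, t, kernel_spec("linear_basis"), cv_cfg = cvc)
  expect_identical(res, res2)
  expect_error(repeated_kfold_cv(X[1:3, ], t[1:3], cv_cfg = cv_config(folds = 10)),
               "folds")
})

test_that("model selection returns the argmax and a full comparison table", {
  cfg <- sim_config(n_individuals = 120, n_markers = 40, k_causal = 3,
                    h2 = 0.8, ld_rho = 0.2, seed = 33)
  d <- simulate_dataset(cfg)
  cands <- list(kernel_spec("linear_basis"), kernel_spec("gaussian", gamma = 2e-4))
  sel <- select_model(d$X, d$t, cands,
                      cv_cfg = cv_config(repeats = 1, folds = 3, seed = 2))
  expect_equal(nrow(sel$table), 2)
  expect_equal(sel$best_result$mean_r2, max(sel$table$mean_r2))
  # single candidate comes straight back
  one <- select_model(d$X, d$t, cands[1],
                      cv_cfg = cv_config(repeats = 1, folds = 3, seed = 2))
  expect_identical(one$best$family, "linear_basis")
  # candidate order does not change the winner
  sel_rev <- select_model(d$X, d$t, rev(cands),
                          cv_cfg = cv_config(repeats = 1, folds = 3, seed = 2))
  expect_identical(sel$best$family, sel_rev$best$family)
})

test_that("ties in model selection go to the simpler family", {
  specs <- list(kernel_spec("gaussian", gamma = 3e-4),
                kernel_spec("gaussian", gamma = 1e-4),
                kernel_spec("polynomial", c = 1, d = 2),
                kernel_spec("linear"),
                kernel_spec("linear_basis"))
  cx <- t(vapply(specs, rvmsel:::.family_complexity, numeric(2)))
  r2 <- rep(0.5, 5)  # exact tie everywhere
  winner <- specs[[order(-r2, cx[, 1], cx[, 2])[1]]]
  expect_identical(winner$family, "linear_basis")
  # among gaussians alone, the smaller bandwidth wins a tie
  gx <- cx[1:2, ]
  expect_identical(order(gx[, 2])[1], 2L)
})

test_that("per-repeat spread is small on a stable synthetic scenario", {
  cfg <- sim_config(n_individuals = 150, n_markers = 100, k_causal = 5,
                    h2 = 0.7, seed = 35)
  d <- simulate_dataset(cfg)
  res <- repeated_kfold_cv(d$X, d$t, kernel_spec("linear_basis"),
                           cv_cfg = cv_config(repeats = 3, folds = 5, seed = 4))
  expect_lt(res$std_r2, 0.05)
  # pooled-fold mean and repeat-mean aggregation agree closely
  expect_lt(abs(mean(res$per_fold_r2) - res$mean_r2), 0.02)
})

test_that("held-out accuracy grows toward heritability with sample size", {
  r2s <- sapply(c(150, 400), function(n) {
    cfg <- sim_config(n_individuals = n, n_markers = 300, k_causal = 10,
                      h2 = 0.6, seed = 36)
    d <- simulate_dataset(cfg)
    res <- repeated_kfold_cv(d$X, d$t, kernel_spec("linear_basis"),
                             cv_cfg = cv_config(repeats = 1, folds = 4, seed = 6))
    c(res$mean_r2, d$truth$realized_h2)
  })
  expect_gt(r2s[1, 2], r2s[1, 1])          # larger N predicts better
  expect_lt(r2s[1, 2], r2s[2, 2] + 0.05)   # bounded by realized h2
  expect_lt(r2s[1, 1], r2s[2, 1] + 0.05)
})
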