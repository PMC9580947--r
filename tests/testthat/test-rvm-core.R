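test_that("build_design_matrix lays out basis and kernel designs", {
  X <- rbind(c(0, 1), c(1, 0))
  Phi <- build_design_matrix(X, kernel_spec("linear_basis"))
  expect_equal(unclass(Phi)[, ], rbind(c(1, 0, 1), c(1, 1, 0)),
               ignore_attr = TRUE)
  expect_identical(attr(Phi, "basis_kind"), "linear_basis")
  expect_identical(attr(Phi, "column_meaning"),
                   c("intercept", "feature", "feature"))

  K <- build_design_matrix(diag(2), kernel_spec("linear"))
  expect_equal(K, diag(2), ignore_attr = TRUE)

  set.seed(3)
  Xr <- matrix(rbinom(40, 1, 0.5), 8, 5)
  G <- build_design_matrix(Xr, kernel_spec("gaussian", gamma = 0.4))
  expect_equal(unname(diag(G)), rep(1, 8))

  Gi <- build_design_matrix(Xr, kernel_spec("gaussian", gamma = 0.4),
                            include_kernel_intercept = TRUE)
  expect_equal(ncol(Gi), 9)
  expect_equal(Gi[, 1], rep(1, 8), ignore_attr = TRUE)
})

test_that("build_design_matrix rejects bad genotype input", {
  expect_error(build_design_matrix(matrix(c(0, 1, 2, 1), 2, 2),
                                   kernel_spec("linear_basis")),
               "\\{0,1\\}")
  expect_error(build_design_matrix(matrix(0, 1, 3), kernel_spec("linear_basis")),
               "at least 2")
  # kernel mode accepts arbitrary reals
  expect_silent(build_design_matrix(matrix(rnorm(12), 4, 3),
                                    kernel_spec("linear")))
})

test_that("posterior_stats solves the regularized normal equations", {
  ps <- posterior_stats(diag(2), c(2, 4), c(1, 1), 1)
  expect_equal(ps$Sigma, 0.5 * diag(2))
  expect_equal(ps$mu, c(1, 2))

  # an effectively infinite precision pins its weight to zero
  set.seed(8)
  Phi <- matrix(rnorm(30), 10, 3)
  t <- rnorm(10)
  ps2 <- posterior_stats(Phi, t, c(1, 1e12, 1), 0.5)
  expect_lt(abs(ps2$mu[2]), 1e-6)
})

test_that("posterior_stats matches a dense-inverse oracle on random instances", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:30, 1); k <- sample(1:8, 1)
    Phi <- matrix(rnorm(n * k), n, k)
    t <- rnorm(n)
    alpha <- runif(k, 0.1, 5)
    sigma2 <- runif(1, 0.2, 2)
    ps <- posterior_stats(Phi, t, alpha, sigma2)
    Sigma_oracle <- solve(crossprod(Phi) / sigma2 + diag(alpha, k))
    mu_oracle <- drop(Sigma_oracle %*% crossprod(Phi, t)) / sigma2
    expect_equal(ps$Sigma, Sigma_oracle, tolerance = 1e-8)
    expect_equal(ps$mu, mu_oracle, tolerance = 1e-8)
    expect_equal(ps$Sigma, t(ps$Sigma), tolerance = 1e-12)
  }
})

test_that("posterior_stats validates its inputs", {
  expect_error(posterior_stats(diag(2), c(1, 2), c(-1, 1), 1), "alpha")
  expect_error(posterior_stats(diag(2), c(1, 2), c(1, 1), 0), "sigma2")
})

test_that("hyperparameter updates follow the re-estimation formulas", {
  # alpha: (1 - alpha * Sigma_ii) / mu^2 with alpha = 1, Sigma_ii = 0.5, mu = 1
  upd <- update_hyperparameters(matrix(1, 2, 1), c(1, 1),
                                alpha = 1, sigma2 = 1,
                                Sigma = matrix(0.5), mu = 1)
  expect_equal(upd$alpha, 0.5)

  # sigma2: residual^2 / (N - sum gamma) with constructed quantities
  Phi <- matrix(c(1, 0), 2, 1)      # residual (0, 1), squared norm 1
  upd2 <- update_hyperparameters(Phi, c(1, 1), alpha = 1, sigma2 = 1,
                                 Sigma = matrix(0), mu = 1)
  expect_equal(upd2$gamma, 1)        # 1 - 1 * 0
  expect_equal(upd2$sigma2, 1)       # 1 / (2 - 1)

  # a zero weight signals pruning
  upd3 <- update_hyperparameters(Phi, c(1, 1), alpha = 1, sigma2 = 1,
                                 Sigma = matrix(0.5), mu = 0,
                                 prune_threshold = 1e12)
  expect_equal(upd3$alpha, 1e12)

  # degenerate fit: effective dof consume every observation
  expect_error(update_hyperparameters(diag(2), c(1, 1), c(1, 1), 1,
                                      Sigma = diag(0, 2), mu = c(1, 1)),
               "degenerate")
})

test_that("log marginal likelihood matches a dense oracle", {
  # fully pruned basis collapses C to sigma2 * I
  s2 <- 0.8; t1 <- 1.3
  ll <- log_marginal_likelihood(matrix(1, 1, 1), t1, 1e16, s2)
  expect_equal(ll, -0.5 * (log(2 * pi * s2) + t1^2 / s2), tolerance = 1e-6)

  for (s in 1:25) {
    set.seed(100 + s)
    n <- sample(5:30, 1); k <- sample(1:8, 1)
    Phi <- matrix(rnorm(n * k), n, k)
    t <- rnorm(n)
    alpha <- runif(k, 0.1, 5)
    sigma2 <- runif(1, 0.2, 2)
    C <- sigma2 * diag(n) + Phi %*% diag(1 / alpha, k) %*% t(Phi)
    oracle <- -0.5 * (n * log(2 * pi) +
                      as.numeric(determinant(C)$modulus) +
                      drop(t %*% solve(C, t)))
    expect_equal(log_marginal_likelihood(Phi, t, alpha, sigma2), oracle,
                 tolerance = 1e-8)
  }
})
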