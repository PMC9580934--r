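test_that("the per-CpG objective is non-decreasing across iterations", {
  coh <- effect_cohort_xgy()
  fit <- fit_tca(coh$X[, 1:60], coh$W, keep_trace = TRUE)
  mono <- vapply(fit$trace, function(tr)
    all(diff(tr) >= -1e-6 * (abs(tr[-length(tr)]) + 1)), logical(1))
  expect_true(all(mono))
  expect_true(all(fit$loglik >= vapply(fit$trace, `[[`, numeric(1), 1L)))
})

test_that("the noiseless identifiable limit recovers the exact linear system", {
  cfg <- scenario_config("xgy", "uni1c", n = 50, m = 20, m_true = 0, k = 3,
                         dirichlet_alpha = c(4, 2, 1),
                         param_ranges = list(mu = c(0.1, 0.9),
                                             sigma = c(0, 0), tau = c(0, 0)),
                         effect_size = 0, seed = 61)
  coh <- simulate_cohort(cfg)          # X = W mu exactly
  fit <- suppressWarnings(fit_tca(coh$X, coh$W))
  oracle <- t(qr.solve(coh$W, coh$X))  # exact solution of W mu = X
  expect_lt(max(abs(fit$mu_hat - oracle)), 1e-6)
})

test_that("model parameters are recovered from model-generated data", {
  cfg <- scenario_config("xgy", "uni1c", n = 2000, m = 150, m_true = 0, k = 3,
                         dirichlet_alpha = c(4, 2, 1), effect_size = 0,
                         seed = 63)
  coh <- simulate_cohort(cfg)
  fit <- fit_tca(coh$X, coh$W)
  rmse_mu <- sqrt(mean((fit$mu_hat - coh$baseline$mu)^2))
  expect_lte(rmse_mu, 0.02)
  rel_sigma2 <- abs(fit$sigma2_hat - coh$baseline$sigma2) /
    coh$baseline$sigma2
  expect_lte(stats::median(rel_sigma2), 0.5)
})

test_that("equal-weight variances reduce the GLS test to the interaction OLS", {
  coh <- effect_cohort_xgy()
  m <- ncol(coh$X); k <- ncol(coh$W)
  params <- structure(list(
    mu_hat = matrix(0.5, m, k, dimnames = list(colnames(coh$X),
                                               colnames(coh$W))),
    sigma2_hat = matrix(0, m, k),
    tau2_hat = rep(1, m), delta_hat = NULL,
    loglik = rep(0, m), n_iter = 1L, converged = rep(TRUE, m)),
    class = "tca_params")
  gls <- tca_test_xgy(coh$X, coh$W, coh$y, params = params)
  ols <- fit_interaction_model(coh$X, coh$W, coh$y)
  expect_lt(max(abs(gls$estimate - ols$estimate)), 1e-6)
  expect_lt(max(abs(gls$p_value - ols$p_value)), 1e-10)
})

test_that("GLS test p-values are uniform under the null", {
  coh <- null_cohort("xgy")
  tab <- tca_test_xgy(coh$X, coh$W, coh$y)
  expect_gt(suppressWarnings(
    stats::ks.test(tab$p_value, "punif")$p.value), 0.01)
})

test_that("permuting the phenotype on an effect cohort keeps alpha nominal", {
  coh <- effect_cohort_xgy()
  set.seed(199)
  y_perm <- sample(coh$y)
  tab <- tca_test_xgy(coh$X, coh$W, y_perm)
  rej <- mean(tab$p_value < 0.05)
  ci <- 0.05 + c(-1, 1) * stats::qnorm(0.995) *
    sqrt(0.05 * 0.95 / nrow(tab))
  expect_gt(rej, ci[1]); expect_lt(rej, ci[2])
})

test_that("the posterior-mean tensor matches quadrature on small instances", {
  set.seed(71)
  worst <- 0
  for (rep in 1:100) {
    w <- as.vector(simulate_proportions(1, c(2, 1), seed = rep))
    mu <- runif(2, 0.2, 0.8)
    sigma2 <- runif(2, 0.02, 0.1)^2
    tau2 <- runif(1, 0.005, 0.02)^2
    x <- sum(w * mu) + rnorm(1, 0, sqrt(sum(w^2 * sigma2) + tau2))
    params <- structure(list(
      mu_hat = matrix(mu, 1, 2), sigma2_hat = matrix(sigma2, 1, 2),
      tau2_hat = tau2, delta_hat = NULL, loglik = 0, n_iter = 1L,
      converged = TRUE), class = "tca_params")
    Zh <- estimate_tensor(matrix(x, 1, 1), matrix(w, 1, 2), params)
    oracle <- posterior_mean_quadrature(x, w, mu, sigma2, tau2)
    worst <- max(worst, max(abs(as.vector(Zh) - oracle)))
    # posterior-mean identity: the mixed posterior mean reproduces the
    # observation-side conditional mean computed by quadrature
    expect_lt(abs(sum(w * as.vector(Zh)) - sum(w * oracle)), 1e-4)
  }
  expect_lt(worst, 1e-4)
})

test_that("tensor limits: exact observation and prior dominance", {
  # k = 1, tau2 = 0, unit proportions: the observation is the component
  n <- 10
  X <- matrix(seq(0.3, 0.6, length.out = n), n, 1,
              dimnames = list(sprintf("s%d", 1:n), "cpg1"))
  W <- matrix(1, n, 1, dimnames = list(rownames(X), "CT1"))
  params1 <- structure(list(
    mu_hat = matrix(0.4, 1, 1), sigma2_hat = matrix(0.01, 1, 1),
    tau2_hat = 0, delta_hat = NULL, loglik = 0, n_iter = 1L,
    converged = TRUE), class = "tca_params")
  Zh <- estimate_tensor(X, W, params1)
  expect_equal(as.vector(Zh), as.vector(X), tolerance = 1e-12)
  # enormous bulk noise: the prior mean dominates
  params2 <- params1
  params2$tau2_hat <- 1e9
  Zh2 <- estimate_tensor(X, W, params2)
  expect_equal(as.vector(Zh2), rep(0.4, n), tolerance = 1e-6)
})

test_that("the Y|X score test is calibrated, degenerate-safe and ranks truth first", {
  coh <- null_cohort("ygx")
  fit <- fit_tca(coh$X, coh$W)
  Zh <- estimate_tensor(coh$X, coh$W, fit)
  tab <- tca_test_ygx(Zh, coh$y)
  expect_gt(suppressWarnings(
    stats::ks.test(tab$p_value, "punif")$p.value), 0.01)

  # an exactly constant tensor column carries no information
  Zc <- Zh
  Zc[, 1, 1] <- 0.5
  tabc <- tca_test_ygx(Zc, coh$y)
  row <- tabc[tabc$cpg == dimnames(Zc)[[2]][1] & tabc$cell_type ==
                dimnames(Zc)[[3]][1], ]
  expect_identical(row$p_value, 1)
  expect_identical(row$statistic, 0)

  # a strong noiseless single-entry Y|X cohort puts the causal pair on top
  hits <- 0
  for (s in 1:10) {
    cfg <- scenario_config("ygx", "uni1c", n = 400, m = 150, m_true = 1,
                           k = 3, dirichlet_alpha = c(4, 2, 1),
                           effect_size = 4, liability_sd = 0,
                           seed = 400 + s)
    co <- simulate_cohort(cfg)
    f <- fit_tca(co$X, co$W)
    tb <- tca_test_ygx(estimate_tensor(co$X, co$W, f), co$y)
    tt <- truth_table(co)
    top <- tb[which.min(tb$p_value), ]
    if (top$cpg == tt$cpg && top$cell_type == tt$cell_type) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the joint Y|X variant partials shared signal and stays conservative", {
  coh <- effect_cohort_xgy()
  fit <- fit_tca(coh$X, coh$W)
  Zh <- estimate_tensor(coh$X, coh$W, fit)
  tab <- tca_test_ygx(Zh, coh$y, joint = TRUE)
  expect_identical(nrow(tab), ncol(coh$X) * ncol(coh$W))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # joint Wald statistics are never larger in aggregate than the marginal
  # ones: the shared bulk residual is partialled out of each coefficient
  marg <- tca_test_ygx(Zh, coh$y)
  expect_lt(mean(abs(tab$statistic)), mean(abs(marg$statistic)))
})

test_that("input contracts are enforced", {
  coh <- effect_cohort_xgy()
  expect_error(fit_tca(coh$X[1:6, ], coh$W[1:6, ]), "n > 2k")
  expect_error(tca_test_xgy(coh$X, coh$W, rep(0, nrow(coh$X))), "constant")
  fit <- fit_tca(coh$X[, 1:10], coh$W)
  expect_error(estimate_tensor(coh$X, coh$W, fit), "do not match")
  Zh <- estimate_tensor(coh$X[, 1:10], coh$W, fit)
  expect_error(tca_test_ygx(Zh, coh$y[1:5]), "length")
})
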