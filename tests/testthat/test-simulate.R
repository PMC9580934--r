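test_that("simulated proportions live on the simplex and are reproducible", {
  W <- simulate_proportions(200, c(7, 2.5, 2, 1.5, 1, 0.5), seed = 3)
  expect_equal(dim(W), c(200L, 6L))
  expect_true(all(W >= 0))
  expect_lt(max(abs(rowSums(W) - 1)), 1e-10)
  expect_identical(W, simulate_proportions(200, c(7, 2.5, 2, 1.5, 1, 0.5),
                                           seed = 3))
  expect_error(simulate_proportions(10, c(1, -1, 1)), "positive")
})

test_that("a degenerate Dirichlet concentrates on one vertex", {
  W <- simulate_proportions(3, c(1e9, 1e-9, 1e-9), seed = 1)
  expect_true(all(abs(W[, 1] - 1) < 1e-6))
  expect_true(all(W[, 2:3] < 1e-6))
})

test_that("proportion column means match the Dirichlet mean", {
  alpha <- c(5, 2, 2, 1, 1, 1)
  W <- simulate_proportions(100000, alpha, seed = 4)
  expect_true(all(abs(colMeans(W) - alpha / sum(alpha)) < 0.01))
})

test_that("baseline draws respect their ranges and seed", {
  pr <- list(mu = c(0.5, 0.5), sigma = c(0.02, 0.1), tau = c(0.005, 0.02))
  b <- simulate_baseline(20, 3, pr, seed = 5)
  expect_true(all(b$mu == 0.5))
  expect_true(all(b$sigma2 > 0) && all(b$tau2 > 0))
  expect_identical(b, simulate_baseline(20, 3, pr, seed = 5))
  # law of large numbers on the uniform sampler
  b2 <- simulate_baseline(10000, 1, list(mu = c(0, 1), sigma = c(0.02, 0.1),
                                         tau = c(0.005, 0.02)), seed = 6)
  expect_lt(abs(mean(b2$mu) - 0.5), 0.01)
  expect_error(
    simulate_baseline(10, 3, list(mu = c(0.9, 0.1), sigma = c(0.02, 0.1),
                                  tau = c(0.005, 0.02))),
    "well-ordered")
})

test_that("effect assignment matches the scenario definitions", {
  base <- list(n = 100, m = 200, k = 6, seed = 9)
  # null benchmark: zero effect size means a zero matrix
  cfg0 <- scenario_config("xgy", "uni1c", n = 100, m = 200, m_true = 20,
                          effect_size = 0, seed = 9)
  expect_true(all(assign_effects(cfg0)$beta == 0))

  cfg1 <- scenario_config("xgy", "uni1c", n = 100, m = 200, m_true = 5,
                          effect_size = 2, seed = 9)
  tr1 <- assign_effects(cfg1)
  expect_identical(sum(tr1$beta != 0), 5L)
  expect_true(all(rowSums(tr1$beta != 0)[tr1$affected_cpgs] == 1))
  expect_true(all(tr1$beta[tr1$beta != 0] == 2))  # one sign in uni scenarios

  # exhaustive scan: bi2c has exactly one + and one - per affected CpG
  cfg2 <- scenario_config("xgy", "bi2c", n = 100, m = 200, m_true = 50,
                          effect_size = 1.5, seed = 10)
  tr2 <- assign_effects(cfg2)
  expect_identical(sum(tr2$beta != 0), 100L)
  for (j in tr2$affected_cpgs) {
    expect_identical(sum(tr2$beta[j, ] > 0), 1L)
    expect_identical(sum(tr2$beta[j, ] < 0), 1L)
    expect_true(all(abs(tr2$beta[j, tr2$beta[j, ] != 0]) == 1.5))
  }

  # bi3c: three affected cell types, both signs present in each CpG
  cfg3 <- scenario_config("xgy", "bi3c", n = 100, m = 200, m_true = 30,
                          effect_size = 1, seed = 11)
  tr3 <- assign_effects(cfg3)
  counts <- rowSums(tr3$beta != 0)[tr3$affected_cpgs]
  expect_true(all(counts == 3))
  signs_ok <- vapply(tr3$affected_cpgs, function(j) {
    s <- tr3$beta[j, tr3$beta[j, ] != 0]
    any(s > 0) && any(s < 0)
  }, logical(1))
  expect_true(all(signs_ok))

  expect_error(scenario_config("xgy", "uni1c", m = 10, m_true = 11), "exceed")
  expect_error(scenario_config("xgy", "bi3c", k = 2,
                               dirichlet_alpha = c(1, 1)), "needs 3")
})

test_that("scenario cardinality holds exhaustively across scenarios", {
  per <- c(uni1c = 1L, uni2c = 2L, bi2c = 2L, bi3c = 3L)
  for (sc in names(per)) {
    cfg <- scenario_config("xgy", sc, n = 50, m = 120, m_true = 15,
                           effect_size = 1, seed = 13)
    expect_identical(sum(assign_effects(cfg)$beta != 0), 15L * per[[sc]])
  }
})

test_that("the mixture identity and seed determinism hold for both directions", {
  for (d in c("xgy", "ygx")) {
    cfg <- scenario_config(d, "uni2c", n = 80, m = 50, m_true = 5, k = 3,
                           dirichlet_alpha = c(4, 2, 1), effect_size = 2,
                           seed = 31)
    coh <- simulate_cohort(cfg)
    expect_lt(max(abs(coh$X - reconstruct_bulk(coh))), 1e-10)
    coh2 <- simulate_cohort(cfg)
    expect_identical(coh$X, coh2$X)
    expect_identical(coh$Z, coh2$Z)
    expect_identical(coh$y, coh2$y)
  }
})

test_that("a noiseless degenerate cohort equals the mixed baseline means", {
  cfg <- scenario_config("xgy", "uni1c", n = 40, m = 20, m_true = 0, k = 3,
                         dirichlet_alpha = c(4, 2, 1),
                         param_ranges = list(mu = c(0.1, 0.9),
                                             sigma = c(0, 0), tau = c(0, 0)),
                         effect_size = 0, seed = 41)
  coh <- simulate_cohort(cfg)
  expect_equal(unname(coh$X), unname(coh$W %*% t(coh$baseline$mu)),
               tolerance = 1e-12)
})

test_that("X|Y case shifts at affected CpGs match the mixture expectation", {
  # at a large standardized effect, the case-control difference in bulk
  # levels equals E[W_h] * effect * sigma_hj up to Monte-Carlo error
  cfg <- scenario_config("xgy", "uni1c", n = 4000, m = 50, m_true = 5, k = 3,
                         dirichlet_alpha = c(4, 2, 1), effect_size = 4,
                         seed = 43)
  coh <- simulate_cohort(cfg)
  tt <- truth_table(coh)
  for (r in seq_len(nrow(tt))) {
    j <- tt$cpg[r]; h <- tt$cell_type[r]
    obs <- mean(coh$X[coh$y == 1, j]) - mean(coh$X[coh$y == 0, j])
    expval <- mean(coh$W[, h]) * tt$beta[r] *
      sqrt(coh$baseline$sigma2[j, h])
    expect_lt(abs(obs - expval), 4 * 0.1 / sqrt(1000))
  }
})

test_that("Y|X cohorts are balanced and the liability is re-derivable", {
  cfg <- scenario_config("ygx", "uni1c", n = 101, m = 40, m_true = 1, k = 3,
                         dirichlet_alpha = c(4, 2, 1), effect_size = 4,
                         liability_sd = 0, seed = 47)
  coh <- simulate_cohort(cfg)
  expect_identical(sum(coh$y == 1), 51L)   # ceiling(n/2) cases
  expect_identical(sum(coh$y == 0), 50L)
  # zero liability noise, single truth entry: y is the indicator of the
  # latent value at that entry exceeding its median, recomputable from Z
  tt <- truth_table(coh)
  zvals <- coh$Z[, tt$cpg, tt$cell_type] * sign(tt$beta)
  expect_identical(unname(coh$y),
                   as.integer(rank(-zvals, ties.method = "first") <=
                                ceiling(cfg$n / 2)))
})

test_that("a null Y|X phenotype is independent of the latent tensor", {
  cfg <- scenario_config("ygx", "uni1c", n = 400, m = 50, m_true = 5, k = 3,
                         dirichlet_alpha = c(4, 2, 1), effect_size = 0,
                         seed = 53)
  coh <- simulate_cohort(cfg)
  cors <- apply(coh$Z, c(2, 3), function(z) cor(z, coh$y))
  expect_lt(max(abs(cors)), 5 / sqrt(400))
})
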