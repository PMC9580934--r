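# Shared miniature study conditions for the unit tests. Cohorts are cached
# per test run so several test files can reuse the same simulated data.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, config) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, simulate_cohort(config), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# medium null cohorts for calibration checks
null_cohort <- function(direction = "xgy", seed = 11L, m = 600) {
  cached_cohort(paste0("null-", direction, "-", seed, "-", m),
                scenario_config(direction, "uni1c", n = 500, m = m,
                                m_true = 10, effect_size = 0, seed = seed))
}

# small cohort with strong single-cell-type effects, X|Y truth
effect_cohort_xgy <- function(seed = 21L) {
  cached_cohort(paste0("xgy-", seed),
                scenario_config("xgy", "uni1c", n = 300, m = 200, m_true = 10,
                                k = 3, dirichlet_alpha = c(4, 2, 1),
                                effect_size = 3, seed = seed))
}

# independent step-up implementation used as the BH oracle
bh_flags_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= alpha * seq_len(m) / m)
  flags <- rep(FALSE, m)
  if (length(passed) > 0)
    flags[ord[seq_len(max(passed))]] <- TRUE
  flags
}

# brute-force posterior mean of z (k-dim) given x = w'z + e by Riemann
# integration on a grid; independent of the package's closed forms
posterior_mean_quadrature <- function(x, w, mu, sigma2, tau2, half_width = 6,
                                      n_grid = 201) {
  k <- length(w)
  grids <- lapply(seq_len(k), function(h)
    seq(mu[h] - half_width * sqrt(sigma2[h]),
        mu[h] + half_width * sqrt(sigma2[h]), length.out = n_grid))
  pts <- as.matrix(expand.grid(grids))
  prior <- rep(1, nrow(pts))
  for (h in seq_len(k))
    prior <- prior * stats::dnorm(pts[, h], mu[h], sqrt(sigma2[h]))
  lik <- stats::dnorm(x, as.vector(pts %*% w), sqrt(tau2))
  wts <- prior * lik
  colSums(pts * wts) / sum(wts)
}
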