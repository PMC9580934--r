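#' Simulate cell-type proportions on the simplex
#'
#' Draws each sample's cell-type composition from a Dirichlet distribution
#' (independent gamma draws normalized to sum to one), the standard model for
#' constrained compositions such as blood cell fractions.
#'
#' @param n number of samples.
#' @param dirichlet_alpha positive concentration vector of length `k`.
#' @param seed integer seed.
#' @return an `n x k` matrix with non-negative rows summing to 1.
#' @examples
#' W <- simulate_proportions(5, c(7, 2.5, 2, 1.5, 1, 0.5), seed = 1)
#' rowSums(W)
#' @export
simulate_proportions <- function(n, dirichlet_alpha, seed = 1L) {
  n <- assert_scalar_count(n, "n")
  if (any(!is.finite(dirichlet_alpha)) || any(dirichlet_alpha <= 0))
    stop_param("`dirichlet_alpha` must be strictly positive and finite")
  k <- length(dirichlet_alpha)
  W <- with_seed(seed, {
    g <- matrix(stats::rgamma(n * k, shape = rep(dirichlet_alpha, each = n)),
                nrow = n, ncol = k)
    rs <- rowSums(g)
    # gamma draws with tiny shapes can underflow to an all-zero row; fall
    # back to the distribution mean for such rows
    bad <- rs <= 0 | !is.finite(rs)
    if (any(bad)) {
      g[bad, ] <- matrix(dirichlet_alpha / sum(dirichlet_alpha),
                         nrow = sum(bad), ncol = k, byrow = TRUE)
      rs[bad] <- 1
    }
    g / rs
  })
  dimnames(W) <- list(sample_ids(n), celltype_ids(k))
  W
}

#' Simulate baseline methylation parameters
#'
#' Draws, independently per (CpG, cell type), a baseline mean methylation
#' level and a latent per-cell-type standard deviation, plus one bulk
#' measurement-noise standard deviation per CpG, each uniformly from its
#' configured range. Magnitudes are on the beta-value scale of array
#' methylation data.
#'
#' @param m number of CpGs.
#' @param k number of cell types.
#' @param param_ranges list with increasing length-2 ranges `mu`, `sigma`,
#'   `tau` (see [scenario_config()]).
#' @param seed integer seed.
#' @return list with `mu` (`m x k` means), `sigma2` (`m x k` latent
#'   variances), `tau2` (length-`m` bulk noise variances).
#' @export
simulate_baseline <- function(m, k,
                              param_ranges = list(mu = c(0.1, 0.9),
                                                  sigma = c(0.02, 0.1),
                                                  tau = c(0.005, 0.02)),
                              seed = 1L) {
  m <- assert_scalar_count(m, "m")
  k <- assert_scalar_count(k, "k")
  for (nm in c("mu", "sigma", "tau")) {
    r <- param_ranges[[nm]]
    if (is.null(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop_param("`param_ranges$%s` must be a well-ordered length-2 range", nm)
  }
  out <- with_seed(seed, {
    mu <- matrix(stats::runif(m * k, param_ranges$mu[1], param_ranges$mu[2]),
                 m, k)
    sigma <- matrix(stats::runif(m * k, param_ranges$sigma[1],
                                 param_ranges$sigma[2]), m, k)
    tau <- stats::runif(m, param_ranges$tau[1], param_ranges$tau[2])
    list(mu = mu, sigma2 = sigma^2, tau2 = tau^2)
  })
  dimnames(out$mu) <- dimnames(out$sigma2) <- list(cpg_ids(m), celltype_ids(k))
  names(out$tau2) <- cpg_ids(m)
  out
}

#' Assign ground-truth cell-type-level effects
#'
#' Picks `m_true` affected CpGs and, per affected CpG, the scenario's number
#' of affected cell types, with signs following the scenario family: "uni"
#' scenarios carry a single common sign, "bi" scenarios mix positive and
#' negative effects within every affected CpG. Effect magnitudes are stored
#' in standardized units (multiples of the latent per-cell-type standard
#' deviation); the cohort simulators scale them by the baseline
#' \eqn{\sigma_{hj}} when the effects enter the data.
#'
#' @param config a [scenario_config()].
#' @return an object of class `effect_truth`: list with `beta` (`m x k`
#'   signed standardized effects), `affected_cpgs` (integer indices) and
#'   `affected_map` (per affected CpG, a named sign vector over cell-type
#'   indices).
#' @export
assign_effects <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  m <- config$m; k <- config$k; e <- config$effect_size
  n_cells <- scenario_cells(config$scenario)
  beta <- matrix(0, m, k, dimnames = list(cpg_ids(m), celltype_ids(k)))
  affected_map <- list()
  affected <- integer(0)
  if (config$m_true > 0) {
    drawn <- with_seed(config$truth_seed %||% (config$seed + 2L), {
      cpgs <- sort(sample.int(m, config$m_true))
      per_cpg <- lapply(cpgs, function(j) {
        cells <- sample.int(k, n_cells)
        signs <- effect_signs(config$scenario, n_cells)
        stats::setNames(signs, cells)
      })
      list(cpgs = cpgs, per_cpg = per_cpg)
    })
    affected <- drawn$cpgs
    affected_map <- stats::setNames(drawn$per_cpg, cpg_ids(m)[affected])
    if (e > 0) {
      for (i in seq_along(affected)) {
        s <- drawn$per_cpg[[i]]
        beta[affected[i], as.integer(names(s))] <- s * e
      }
    }
  }
  structure(list(beta = beta,
                 affected_cpgs = if (e > 0) affected else integer(0),
                 affected_map = if (e > 0) affected_map else list()),
            class = "effect_truth")
}

# sign pattern for one affected CpG
effect_signs <- function(scenario, n_cells) {
  switch(scenario,
    uni1c = 1,
    uni2c = c(1, 1),
    bi2c = sample(c(1, -1)),
    bi3c = sample(c(1, -1, sample(c(1, -1), 1L))),
    stop_param("unknown scenario '%s'", scenario))
}

#' Ground-truth table of nonzero effects
#'
#' @param x an `effect_truth` or `synthetic_cohort`.
#' @return data.frame with columns `cpg`, `cell_type`, `beta` (standardized
#'   signed effect), one row per nonzero truth entry.
#' @export
truth_table <- function(x) {
  truth <- if (inherits(x, "synthetic_cohort")) x$truth else x
  stopifnot(inherits(truth, "effect_truth"))
  idx <- which(truth$beta != 0, arr.ind = TRUE)
  out <- data.frame(cpg = rownames(truth$beta)[idx[, 1]],
                    cell_type = colnames(truth$beta)[idx[, 2]],
                    beta = truth$beta[idx],
                    stringsAsFactors = FALSE)
  out[order(out$cpg, out$cell_type), , drop = FALSE]
}

#' Simulate a synthetic bulk-methylation cohort
#'
#' Generates a cohort from the component-mixture model: latent per-cell-type
#' methylation \eqn{Z_{ihj} \sim N(\mu_{hj}, \sigma^2_{hj})} combined into
#' bulk values \eqn{X_{ij} = \sum_h W_{ih} Z_{ihj} + e_{ij}},
#' \eqn{e_{ij} \sim N(0, \tau^2_j)}, with the phenotype attached in the
#' direction named by the configuration:
#'
#' * X|Y (`direction = "xgy"`): a balanced binary phenotype is drawn first
#'   and shifts the latent mean of every truth entry by
#'   \eqn{\beta_{hj}\sigma_{hj} y_i};
#' * Y|X (`direction = "ygx"`): the latent tensor is drawn with no phenotype
#'   term; a liability \eqn{L_i = \sum_{(j,h)} \beta_{hj}\sigma_{hj} Z_{ihj}
#'   + \epsilon_i} accumulates the truth entries, and cases are the samples
#'   above the median liability (exactly \eqn{\lceil n/2\rceil} cases).
#'
#' All randomness is a deterministic function of `config$seed` (sub-seeds for
#' proportions, baseline, effect assignment and cohort draws are derived as
#' fixed offsets of it).
#'
#' @param config a [scenario_config()].
#' @return an object of class `synthetic_cohort`: list with bulk matrix `X`
#'   (`n x m`, samples by CpGs), proportions `W` (`n x k`), phenotype `y`
#'   (0/1 integer vector), latent tensor `Z` (`n x m x k` array), retained
#'   bulk noise `noise` (`n x m`), `baseline` parameters, `truth`
#'   ([assign_effects()] output), `liability` (Y|X only: the liability
#'   vector and its noise sd) and `config`.
#' @examples
#' cfg <- scenario_config("xgy", "uni1c", n = 60, m = 30, m_true = 3, k = 3,
#'                        dirichlet_alpha = c(4, 2, 1), effect_size = 2,
#'                        seed = 7)
#' coh <- simulate_cohort(cfg)
#' dim(coh$X)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n; m <- config$m; k <- config$k
  W <- simulate_proportions(n, config$dirichlet_alpha, seed = config$seed)
  base <- simulate_baseline(m, k, config$param_ranges, seed = config$seed + 1L)
  truth <- assign_effects(config)
  sigma <- sqrt(base$sigma2)
  tau <- sqrt(base$tau2)

  draws <- with_seed(config$seed + 3L, {
    if (config$direction == "xgy") {
      y <- as.integer(sample(rep(c(1L, 0L), c(ceiling(n / 2), floor(n / 2)))))
      Z <- array(0, dim = c(n, m, k))
      for (h in seq_len(k)) {
        shift <- truth$beta[, h] * sigma[, h]  # Z-scale case shift
        Z[, , h] <- matrix(stats::rnorm(n * m), n, m) *
          matrix(sigma[, h], n, m, byrow = TRUE) +
          matrix(base$mu[, h], n, m, byrow = TRUE) +
          y %o% shift
      }
      list(y = y, Z = Z, liability = NULL)
    } else {
      Z <- array(0, dim = c(n, m, k))
      for (h in seq_len(k)) {
        Z[, , h] <- matrix(stats::rnorm(n * m), n, m) *
          matrix(sigma[, h], n, m, byrow = TRUE) +
          matrix(base$mu[, h], n, m, byrow = TRUE)
      }
      entries <- which(truth$beta != 0, arr.ind = TRUE)
      L <- numeric(n)
      sig_var1 <- 0  # liability signal variance at unit effect
      if (nrow(entries) > 0) {
        for (r in seq_len(nrow(entries))) {
          j <- entries[r, 1]; h <- entries[r, 2]
          w_e <- truth$beta[j, h] * sigma[j, h]
          L <- L + w_e * Z[, j, h]
          sig_var1 <- sig_var1 + sigma[j, h]^4
        }
      }
      noise_sd <- config$liability_sd %||% sqrt(sig_var1)
      if (noise_sd == 0 && nrow(entries) == 0) noise_sd <- 1
      L <- L + stats::rnorm(n, 0, noise_sd)
      y <- integer(n)
      y[order(L, decreasing = TRUE)[seq_len(ceiling(n / 2))]] <- 1L
      list(y = y, Z = Z, liability = list(L = L, noise_sd = noise_sd))
    }
  })

  E <- with_seed(config$seed + 4L, {
    matrix(stats::rnorm(n * m), n, m) * matrix(tau, n, m, byrow = TRUE)
  })
  X <- E
  for (h in seq_len(k)) X <- X + draws$Z[, , h] * W[, h]
  if (config$clip) X <- pmin(pmax(X, 0), 1)
  dimnames(X) <- list(sample_ids(n), cpg_ids(m))
  dimnames(E) <- dimnames(X)
  dimnames(draws$Z) <- list(sample_ids(n), cpg_ids(m), celltype_ids(k))
  names(draws$y) <- sample_ids(n)

  structure(list(X = X, W = W, y = draws$y, Z = draws$Z, noise = E,
                 baseline = base, truth = truth, liability = draws$liability,
                 covariates = NULL, config = config),
            class = "synthetic_cohort")
}

#' Recombine the retained latent tensor into bulk values
#'
#' Reconstructs `X` from the stored tensor, proportions and noise draws;
#' useful for verifying the mixture identity of a cohort.
#'
#' @param cohort a `synthetic_cohort`.
#' @return an `n x m` matrix equal to `cohort$X` up to clipping.
#' @export
reconstruct_bulk <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  X <- cohort$noise
  for (h in seq_len(cohort$config$k)) X <- X + cohort$Z[, , h] * cohort$W[, h]
  X
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %s/%s  n=%d m=%d k=%d  %d truth entries  (seed %d)\n",
    toupper(x$config$direction), x$config$scenario, x$config$n, x$config$m,
    x$config$k, sum(x$truth$beta != 0), x$config$seed))
  cat(sprintf("  cases:controls = %d:%d\n", sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}
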