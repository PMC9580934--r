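#' Benchmark scenario configuration
#'
#' Bundles every knob of the synthetic-cohort generator into one validated
#' object. The four named scenarios control how many cell types carry a true
#' effect at each affected CpG and whether the effect signs agree:
#'
#' * `"uni1c"` — one affected cell type per CpG, one sign;
#' * `"uni2c"` — two affected cell types, same sign;
#' * `"bi2c"`  — two affected cell types, opposite signs;
#' * `"bi3c"`  — three affected cell types, mixed signs.
#'
#' `direction` selects the true generative directionality: `"xgy"` simulates
#' methylation shifted by the phenotype (X|Y); `"ygx"` simulates a phenotype
#' driven by latent cell-type methylation through a liability threshold
#' (Y|X).
#'
#' @param direction `"xgy"` or `"ygx"`.
#' @param scenario one of `"uni1c"`, `"uni2c"`, `"bi2c"`, `"bi3c"`.
#' @param n number of samples.
#' @param m number of CpGs.
#' @param m_true number of truly associated CpGs.
#' @param k number of cell types.
#' @param effect_size standardized effect size: the per-cell-type shift (X|Y)
#'   or liability weight (Y|X) in units of the latent cell-type standard
#'   deviation at that CpG.
#' @param dirichlet_alpha length-`k` positive concentration vector for the
#'   cell-type proportions. The default is blood-like: one dominant cell type
#'   and progressively rarer subsets.
#' @param param_ranges list with components `mu`, `sigma`, `tau`, each a
#'   length-2 increasing range, for the baseline per-cell-type means, the
#'   latent per-cell-type standard deviations and the bulk measurement-noise
#'   standard deviation.
#' @param liability_sd standard deviation of the Gaussian liability noise used
#'   in Y|X mode, or `NULL` (default) for the automatic rule: the noise
#'   variance equals the liability signal variance at `effect_size = 1`, so
#'   the liability heritability at effect size \eqn{e} is \eqn{e^2/(1+e^2)}.
#' @param clip logical; clip bulk values into \[0, 1\] after mixing (default
#'   `FALSE` so that Gaussian oracle computations stay exact).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param truth_seed optional integer seed controlling only the effect
#'   assignment (which CpGs/cell types are affected, and the signs). Two
#'   configurations sharing `truth_seed` but differing in `seed` yield
#'   independent cohorts with identical ground truth -- the replication
#'   setting of the cross-dataset validation-rate analysis. Default
#'   (`NULL`): derived from `seed`.
#' @return an object of class `scenario_config` (a validated list).
#' @examples
#' cfg <- scenario_config("xgy", "uni1c", n = 100, m = 50, m_true = 5,
#'                        effect_size = 2, seed = 1)
#' cfg
#' @export
scenario_config <- function(direction = c("xgy", "ygx"),
                            scenario = c("uni1c", "uni2c", "bi2c", "bi3c"),
                            n = 500, m = 1000, m_true = 10, k = 6,
                            effect_size = 1,
                            dirichlet_alpha = c(7.0, 2.5, 2.0, 1.5, 1.0, 0.5),
                            param_ranges = list(mu = c(0.1, 0.9),
                                                sigma = c(0.02, 0.1),
                                                tau = c(0.005, 0.02)),
                            liability_sd = NULL,
                            clip = FALSE,
                            seed = 1L,
                            truth_seed = NULL) {
  direction <- match.arg(direction)
  scenario <- match.arg(scenario)
  n <- assert_scalar_count(n, "n")
  m <- assert_scalar_count(m, "m")
  k <- assert_scalar_count(k, "k")
  if (!is.numeric(m_true) || length(m_true) != 1L || m_true < 0 ||
      m_true != floor(m_true))
    stop_param("`m_true` must be a single non-negative integer")
  m_true <- as.integer(m_true)
  if (m_true > m)
    stop_param("`m_true` (%d) cannot exceed `m` (%d)", m_true, m)
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0)
    stop_param("`effect_size` must be a single non-negative number")
  if (length(dirichlet_alpha) != k)
    stop_param("`dirichlet_alpha` must have length k = %d", k)
  if (any(!is.finite(dirichlet_alpha)) || any(dirichlet_alpha <= 0))
    stop_param("`dirichlet_alpha` must be strictly positive")
  n_affected <- scenario_cells(scenario)
  if (n_affected > k)
    stop_param("scenario '%s' needs %d affected cell types but k = %d",
               scenario, n_affected, k)
  for (nm in c("mu", "sigma", "tau")) {
    r <- param_ranges[[nm]]
    if (is.null(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop_param("`param_ranges$%s` must be a well-ordered length-2 range", nm)
  }
  if (any(param_ranges$sigma < 0) || any(param_ranges$tau < 0))
    stop_param("sigma and tau ranges must be non-negative")
  if (!is.null(liability_sd) &&
      (!is.numeric(liability_sd) || length(liability_sd) != 1L || liability_sd < 0))
    stop_param("`liability_sd` must be NULL or a single non-negative number")
  structure(
    list(direction = direction, scenario = scenario, n = n, m = m,
         m_true = m_true, k = k, effect_size = effect_size,
         dirichlet_alpha = as.numeric(dirichlet_alpha),
         param_ranges = param_ranges[c("mu", "sigma", "tau")],
         liability_sd = liability_sd, clip = isTRUE(clip),
         seed = as.integer(seed),
         truth_seed = if (!is.null(truth_seed)) as.integer(truth_seed)),
    class = "scenario_config")
}

# affected cell types per CpG for each named scenario
scenario_cells <- function(scenario) {
  switch(scenario, uni1c = 1L, uni2c = 2L, bi2c = 2L, bi3c = 3L,
         stop_param("unknown scenario '%s'", scenario))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %s / %s  n=%d m=%d (m_true=%d) k=%d effect=%.3g seed=%d\n",
    toupper(x$direction), x$scenario, x$n, x$m, x$m_true, x$k,
    x$effect_size, x$seed))
  invisible(x)
}
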