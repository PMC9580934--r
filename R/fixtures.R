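fixture_registry <- function() {
  list(
    # a null X|Y cohort: downstream p-values should be uniform
    "null-xgy" = scenario_config("xgy", "uni1c", n = 60, m = 30, m_true = 3,
                                 k = 3, dirichlet_alpha = c(4, 2, 1),
                                 effect_size = 0, seed = 101L),
    # strong single-cell-type effects in the X|Y direction
    "strong-uni1c" = scenario_config("xgy", "uni1c", n = 60, m = 30,
                                     m_true = 3, k = 3,
                                     dirichlet_alpha = c(4, 2, 1),
                                     effect_size = 4, seed = 102L),
    # strong Y|X cohort with noiseless liability
    "strong-ygx" = scenario_config("ygx", "uni1c", n = 60, m = 30, m_true = 3,
                                   k = 3, dirichlet_alpha = c(4, 2, 1),
                                   effect_size = 4, liability_sd = 0,
                                   seed = 103L),
    # zero latent and bulk variance: X equals the proportion-mixed means
    "degenerate-noiseless" = scenario_config(
      "xgy", "uni1c", n = 60, m = 30, m_true = 0, k = 3,
      dirichlet_alpha = c(4, 2, 1),
      param_ranges = list(mu = c(0.1, 0.9), sigma = c(0, 0), tau = c(0, 0)),
      effect_size = 0, seed = 104L))
}

#' Generate a registered miniature test cohort on disk
#'
#' Deterministic miniature cohorts (n = 60, m = 30, k = 3) used by the test
#' suite and by examples; each registered name exercises one invariant of
#' the generator (see the registry in the source for the intent of each).
#' Calling twice with the same name produces byte-identical files.
#'
#' @param name one of `"null-xgy"`, `"strong-uni1c"`, `"strong-ygx"`,
#'   `"degenerate-noiseless"`.
#' @param dir directory to write into (default: a per-name subdirectory of
#'   `tempdir()`).
#' @return the cohort directory path, invisibly; the in-memory
#'   `synthetic_cohort` as attribute `"cohort"`.
#' @export
make_fixture <- function(name, dir = file.path(tempdir(), paste0("fixture-", name))) {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop_param("unknown fixture '%s'; available: %s", name,
               paste(names(reg), collapse = ", "))
  coh <- simulate_cohort(reg[[name]])
  write_cohort(coh, dir)
  out <- invisible(dir)
  attr(out, "cohort") <- coh
  invisible(out)
}
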