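#' Run the directionality benchmark grid
#'
#' For every combination of true direction, scenario and effect size,
#' simulates `n_reps` replicate cohorts and applies the requested methods:
#'
#' * `"celldmc"` — [fit_interaction_model()] (assumes X|Y);
#' * `"tca_xgy"` — [fit_tca()] + [tca_test_xgy()] (assumes X|Y);
#' * `"tca_ygx"` — [fit_tca()] + [estimate_tensor()] + [tca_test_ygx()]
#'   (assumes Y|X).
#'
#' The latent-model fit is shared between `tca_xgy` and `tca_ygx` within a
#' replicate. Significance is called jointly over the `m * k` tests with
#' [call_significant()] and scored against the simulated truth with
#' [confusion_metrics()]. Replicate seeds follow the fixed rule
#' `master_seed + replicate - 1`, shared across grid cells so that cells
#' differing only in direction or effect size are simulated with common
#' random numbers and can be compared pairwise. When both `"celldmc"` and
#' `"tca_xgy"` are requested, the per-replicate top-`t` consistency score
#' between them (the [directionality_diagnosis()] score at `t` = number of
#' truth entries) is recorded as well.
#'
#' @param directions subset of `c("xgy", "ygx")`: true generative
#'   directionalities to simulate.
#' @param scenarios subset of `c("uni1c", "uni2c", "bi2c", "bi3c")`.
#' @param effect_sizes numeric vector of standardized effect sizes.
#' @param methods subset of `c("celldmc", "tca_xgy", "tca_ygx")`.
#' @param n_reps replicates per grid cell.
#' @param master_seed integer master seed; the whole table is a
#'   deterministic function of it.
#' @param alpha,correction passed to [call_significant()].
#' @param config_args named list of further [scenario_config()] arguments
#'   (`n`, `m`, `m_true`, `k`, ...).
#' @param tca_args named list of further [fit_tca()] arguments.
#' @return object of class `benchmark_result`: list with `metrics` (one row
#'   per cell x method x replicate: SE/SP/PPV, counts, consistency score)
#'   and `summary` (per-cell medians across replicates, mirroring the
#'   solid median lines of the benchmark figures; PPV medians are over the
#'   replicates where at least one call was made).
#' @export
run_benchmark <- function(directions = c("xgy", "ygx"),
                          scenarios = "uni1c",
                          effect_sizes = c(0, 0.5, 1, 2, 4),
                          methods = c("celldmc", "tca_xgy", "tca_ygx"),
                          n_reps = 50,
                          master_seed = 1L,
                          alpha = 0.05,
                          correction = "bonferroni",
                          config_args = list(),
                          tca_args = list()) {
  directions <- match.arg(directions, c("xgy", "ygx"), several.ok = TRUE)
  scenarios <- match.arg(scenarios, c("uni1c", "uni2c", "bi2c", "bi3c"),
                         several.ok = TRUE)
  methods <- match.arg(methods, c("celldmc", "tca_xgy", "tca_ygx"),
                       several.ok = TRUE)
  n_reps <- assert_scalar_count(n_reps, "n_reps")
  grid <- expand.grid(direction = directions, scenario = scenarios,
                      effect_size = effect_sizes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- list()
  want_consistency <- all(c("celldmc", "tca_xgy") %in% methods)
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(n_reps)) {
      seed_r <- master_seed + r - 1L
      cell <- grid[g, ]
      rows[[length(rows) + 1L]] <- tryCatch({
        cfg <- do.call(scenario_config, c(
          list(direction = cell$direction, scenario = cell$scenario,
               effect_size = cell$effect_size, seed = seed_r),
          config_args))
        coh <- simulate_cohort(cfg)
        tables <- list()
        params <- NULL
        if ("celldmc" %in% methods)
          tables$celldmc <- fit_interaction_model(coh$X, coh$W, coh$y)
        if (any(c("tca_xgy", "tca_ygx") %in% methods))
          params <- suppressWarnings(
            do.call(fit_tca, c(list(coh$X, coh$W), tca_args)))
        if ("tca_xgy" %in% methods)
          tables$tca_xgy <- tca_test_xgy(coh$X, coh$W, coh$y, params = params)
        if ("tca_ygx" %in% methods) {
          Zh <- estimate_tensor(coh$X, coh$W, params)
          tables$tca_ygx <- tca_test_ygx(Zh, coh$y)
        }
        n_truth <- sum(coh$truth$beta != 0)
        cons <- if (want_consistency && n_truth > 0)
          directionality_diagnosis(tables$celldmc, tables$tca_xgy,
                                   t = n_truth)$score
        else NA_real_
        do.call(rbind, lapply(names(tables), function(meth) {
          calls <- call_significant(tables[[meth]], alpha = alpha,
                                    correction = correction)
          cm <- confusion_metrics(calls, coh$truth)
          cbind(data.frame(direction_true = cell$direction,
                           scenario = cell$scenario,
                           effect_size = cell$effect_size,
                           method = meth, replicate = r, seed = seed_r,
                           failed = FALSE,
                           consistency = if (meth == "celldmc") cons
                                         else NA_real_),
                cm)
        }))
      }, error = function(e) {
        warning(sprintf("replicate %d of cell %d failed: %s", r, g,
                        conditionMessage(e)), call. = FALSE)
        data.frame(direction_true = cell$direction, scenario = cell$scenario,
                   effect_size = cell$effect_size,
                   method = paste(methods, collapse = "+"),
                   replicate = r, seed = seed_r, failed = TRUE,
                   consistency = NA_real_, SE = NA_real_, SP = NA_real_,
                   PPV = NA_real_, TP = NA, FP = NA, TN = NA, FN = NA,
                   n_calls = NA)
      })
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  ok <- metrics[!metrics$failed, , drop = FALSE]
  key <- interaction(ok$direction_true, ok$scenario, ok$effect_size,
                     ok$method, drop = TRUE)
  summary <- do.call(rbind, lapply(split(ok, key), function(d) {
    data.frame(direction_true = d$direction_true[1], scenario = d$scenario[1],
               effect_size = d$effect_size[1], method = d$method[1],
               n_reps = nrow(d),
               median_SE = stats::median(d$SE, na.rm = TRUE),
               median_SP = stats::median(d$SP, na.rm = TRUE),
               median_PPV = stats::median(d$PPV, na.rm = TRUE),
               mean_consistency = mean(d$consistency, na.rm = TRUE))
  }))
  rownames(summary) <- NULL
  structure(list(metrics = metrics, summary = summary,
                 master_seed = master_seed, alpha = alpha,
                 correction = correction),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d metric rows (master seed %d, %s at alpha=%g)\n",
              nrow(x$metrics), x$master_seed, x$correction, x$alpha))
  print(x$summary, digits = 3)
  invisible(x)
}
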