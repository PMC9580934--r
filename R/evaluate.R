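#' Flag significant associations
#'
#' Applies a multiple-testing procedure jointly over all (CpG, cell type)
#' tests in the table and adds a logical `significant` column. The default
#' procedure used throughout the benchmark is Bonferroni at family level
#' `m * k` with alpha = 0.05, the conservative convention when no threshold
#' is prescribed.
#'
#' @param table an `assoc_table`.
#' @param alpha family-wise (or FDR, for `"bh"`) level.
#' @param correction `"bonferroni"`, `"bh"` (Benjamini-Hochberg step-up) or
#'   `"none"` (per-test threshold).
#' @return the table with a `significant` logical column.
#' @export
call_significant <- function(table, alpha = 0.05,
                             correction = c("bonferroni", "bh", "none")) {
  correction <- match.arg(correction)
  p <- table$p_value
  if (is.null(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop_param("`table$p_value` must be valid p-values in [0, 1]")
  adj <- switch(correction,
                bonferroni = stats::p.adjust(p, method = "bonferroni"),
                bh = stats::p.adjust(p, method = "BH"),
                none = p)
  table$significant <- adj <= alpha
  attr(table, "alpha") <- alpha
  attr(table, "correction") <- correction
  table
}

#' Sensitivity, specificity and precision against the ground truth
#'
#' Scores significance calls over the full (CpG, cell type) grid. A call is
#' a true positive only if both the CpG and the cell type match a nonzero
#' truth entry. Precision (PPV) is undefined when no calls are made and is
#' reported as `NA`, never 0.
#'
#' @param calls an `assoc_table` with a `significant` column (see
#'   [call_significant()]).
#' @param truth an `effect_truth`, a `synthetic_cohort`, or a data.frame
#'   with columns `cpg`, `cell_type` listing the true associations.
#' @return one-row data.frame with `SE`, `SP`, `PPV`, `TP`, `FP`, `TN`,
#'   `FN`, `n_calls`.
#' @export
confusion_metrics <- function(calls, truth) {
  if (is.null(calls$significant))
    stop_param("`calls` has no `significant` column; run call_significant() first")
  truth_df <- if (is.data.frame(truth)) truth else truth_table(truth)
  key <- paste(calls$cpg, calls$cell_type, sep = "\r")
  if (anyDuplicated(key))
    stop_param("`calls` has duplicated (cpg, cell_type) rows")
  tkey <- paste(truth_df$cpg, truth_df$cell_type, sep = "\r")
  if (!all(tkey %in% key))
    stop_param("truth entries %s are absent from the calls table",
               paste(setdiff(tkey, key), collapse = ", "))
  is_true <- key %in% tkey
  sig <- calls$significant
  TP <- sum(sig & is_true); FP <- sum(sig & !is_true)
  FN <- sum(!sig & is_true); TN <- sum(!sig & !is_true)
  data.frame(
    SE = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    SP = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    PPV = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
    TP = TP, FP = FP, TN = TN, FN = FN, n_calls = TP + FP)
}

# top-t (CpG, cell type) pairs by smallest p-value; deterministic tie-break
# by p, then CpG, then cell type
top_pairs <- function(table, t) {
  ord <- order(table$p_value, table$cpg, table$cell_type)
  idx <- ord[seq_len(t)]
  paste(table$cpg[idx], table$cell_type[idx], sep = "\r")
}

#' Cross-dataset validation-rate curve
#'
#' For each `t`, takes the `t` most significant (smallest p-value)
#' (CpG, cell type) pairs of each table and reports the fraction shared:
#' an association replicates only if the same CpG is called in the same cell
#' type in both datasets. Used to compare the cross-cohort consistency of
#' methods when no ground truth is available.
#'
#' @param tableA,tableB `assoc_table`s over the same (CpG, cell type)
#'   universe (e.g. the same method run on two independent cohorts).
#' @param t_values increasing positive integers, each at most `m * k`.
#' @return data.frame of class `validation_curve` with columns `t`, `rate`.
#' @export
validation_rate <- function(tableA, tableB,
                            t_values = c(10, 50, 100, 500, 1000)) {
  keyA <- sort(paste(tableA$cpg, tableA$cell_type, sep = "\r"))
  keyB <- sort(paste(tableB$cpg, tableB$cell_type, sep = "\r"))
  if (!identical(keyA, keyB))
    stop_param("the two tables do not share the same (cpg, cell_type) universe")
  t_values <- as.integer(t_values)
  if (any(t_values < 1) || any(t_values > nrow(tableA)))
    stop_param("t values must lie in [1, %d]", nrow(tableA))
  rate <- vapply(t_values, function(t) {
    length(intersect(top_pairs(tableA, t), top_pairs(tableB, t))) / t
  }, numeric(1))
  structure(data.frame(t = t_values, rate = rate),
            class = c("validation_curve", "data.frame"))
}

#' Method-consistency diagnostic for model directionality
#'
#' When the true directionality of a dataset is unknown, the agreement
#' between the interaction-regression calls and the latent-model X|Y calls
#' carries information: under a true X|Y model the two methods (which both
#' assume X|Y) rank largely the same associations on top, while under a true
#' Y|X model their agreement degrades along with their precision. The score
#' is the top-`t` overlap of the two tables (as in [validation_rate()]);
#' the verdict applies declared, configurable thresholds and is a heuristic,
#' not a calibrated test.
#'
#' @param table_celldmc [fit_interaction_model()] output on the dataset.
#' @param table_tca_xgy [tca_test_xgy()] output on the same dataset.
#' @param t number of top associations to compare.
#' @param thresholds length-2 numeric `c(lower, upper)`: scores at or above
#'   `upper` support X|Y, at or below `lower` support Y|X.
#' @return list of class `direction_diagnosis` with `score`, `verdict`
#'   (`"supports_XgY"`, `"supports_YgX"` or `"inconclusive"`), `t` and
#'   `thresholds`.
#' @export
directionality_diagnosis <- function(table_celldmc, table_tca_xgy, t,
                                     thresholds = c(0.2, 0.8)) {
  if (length(t) != 1L || t < 1)
    stop_param("`t` must be a single integer >= 1")
  score <- validation_rate(table_celldmc, table_tca_xgy, t_values = t)$rate
  verdict <- if (score >= thresholds[2]) "supports_XgY"
             else if (score <= thresholds[1]) "supports_YgX"
             else "inconclusive"
  structure(list(score = score, verdict = verdict, t = as.integer(t),
                 thresholds = thresholds),
            class = "direction_diagnosis")
}

#' @export
print.direction_diagnosis <- function(x, ...) {
  cat(sprintf("<direction_diagnosis> top-%d overlap = %.3f -> %s (thresholds %.2f/%.2f)\n",
              x$t, x$score, x$verdict, x$thresholds[1], x$thresholds[2]))
  invisible(x)
}
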