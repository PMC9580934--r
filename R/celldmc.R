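#' Interaction-regression test for cell-type-level differential methylation
#'
#' The CellDMC-style approach: per CpG, bulk methylation is regressed by
#' ordinary least squares on the cell-type proportions and on the
#' proportion-by-phenotype interaction terms,
#' \deqn{X_{\cdot j} \sim W + W \circ y \; (+\; covariates),}
#' and each interaction coefficient is the estimated cell-type-level effect
#' of the phenotype in that cell type. The model is structurally committed to
#' the X|Y directionality (methylation as the dependent variable). No
#' separate intercept is included: the proportion columns sum to one per
#' sample and span it.
#'
#' Because the design matrix is shared by all CpGs, the normal equations are
#' solved once and applied to the whole bulk matrix at once.
#'
#' @param X `n x m` bulk matrix (samples in rows).
#' @param W `n x k` cell-type proportions, rows on the simplex.
#' @param y length-`n` phenotype (binary 0/1 or continuous).
#' @param covariates optional `n x p` numeric matrix, entering additively.
#' @return an `assoc_table` data.frame with one row per (CpG, cell type):
#'   columns `cpg`, `cell_type`, `estimate`, `std_error`, `statistic`
#'   (t-statistic with `n - (2k + p)` degrees of freedom) and `p_value`
#'   (two-sided).
#' @examples
#' coh <- simulate_cohort(scenario_config("xgy", "uni1c", n = 80, m = 20,
#'                                        m_true = 2, k = 3,
#'                                        dirichlet_alpha = c(4, 2, 1),
#'                                        effect_size = 3, seed = 2))
#' head(fit_interaction_model(coh$X, coh$W, coh$y))
#' @export
fit_interaction_model <- function(X, W, y, covariates = NULL) {
  dat <- check_assoc_inputs(X, W, y, covariates)
  X <- dat$X; W <- dat$W; y <- dat$y; C <- dat$C
  n <- nrow(X); m <- ncol(X); k <- ncol(W)
  D <- cbind(W, W * y, C)
  colnames(D) <- c(colnames(W), paste0(colnames(W), ":y"),
                   if (!is.null(C)) colnames(C))
  df <- n - ncol(D)
  if (df <= 0)
    stop_param("insufficient samples: n = %d but the design has %d columns",
               n, ncol(D))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop_param("singular design: column(s) %s are linearly dependent %s",
               paste(sQuote(bad), collapse = ", "),
               if (length(unique(y)) < 2) "(is `y` constant?)" else "")
  }
  DtD_inv <- chol2inv(chol(crossprod(D)))
  coefs <- DtD_inv %*% crossprod(D, X)           # q x m
  resid <- X - D %*% coefs
  s2 <- colSums(resid^2) / df                    # residual variance per CpG
  inter <- k + seq_len(k)                        # interaction rows
  est <- t(coefs[inter, , drop = FALSE])         # m x k
  se <- sqrt(outer(s2, diag(DtD_inv)[inter]))    # m x k
  tstat <- est / se
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  new_assoc_table(cpgs = colnames(X), cells = colnames(W),
                  estimate = est, std_error = se, statistic = tstat,
                  p_value = pval)
}

# shared input validation for the association tests
check_assoc_inputs <- function(X, W, y, covariates) {
  X <- as.matrix(X); W <- as.matrix(W)
  if (nrow(X) != nrow(W))
    stop_param("X has %d rows but W has %d", nrow(X), nrow(W))
  if (!is.null(y) && length(y) != nrow(X))
    stop_param("y has length %d but X has %d rows", length(y), nrow(X))
  if (any(!is.finite(X)) || any(!is.finite(W)))
    stop_param("X and W must be finite")
  if (any(W < -1e-8))
    stop_param("W has negative entries")
  if (max(abs(rowSums(W) - 1)) > 1e-6)
    stop_param("rows of W must sum to 1")
  if (is.null(colnames(X))) colnames(X) <- cpg_ids(ncol(X))
  if (is.null(colnames(W))) colnames(W) <- celltype_ids(ncol(W))
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != nrow(X))
      stop_param("covariates have %d rows but X has %d", nrow(C), nrow(X))
    if (is.null(colnames(C))) colnames(C) <- paste0("cov", seq_len(ncol(C)))
  }
  list(X = X, W = W, y = if (!is.null(y)) as.numeric(y), C = C)
}

# build the long (CpG, cell type) association data.frame from m x k blocks
new_assoc_table <- function(cpgs, cells, estimate, std_error, statistic,
                            p_value) {
  m <- length(cpgs); k <- length(cells)
  out <- data.frame(
    cpg = rep(cpgs, times = k),
    cell_type = rep(cells, each = m),
    estimate = as.vector(estimate),
    std_error = as.vector(std_error),
    statistic = as.vector(statistic),
    p_value = as.vector(p_value),
    stringsAsFactors = FALSE)
  out <- out[order(out$cpg, out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assoc_table", "data.frame")
  out
}
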