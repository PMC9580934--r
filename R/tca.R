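#' Fit the latent component-mixture model of bulk methylation
#'
#' Per CpG \eqn{j}, bulk methylation is modelled marginally as
#' \deqn{X_{ij} \sim N\!\Big(\sum_h W_{ih}\mu_{hj} \,(+\,c_i^\top\delta_j),\;
#'   \sum_h W_{ih}^2\sigma^2_{hj} + \tau^2_j\Big),}
#' the marginal of the component mixture in which every cell type contributes
#' a latent Gaussian methylation level \eqn{Z_{ihj} \sim N(\mu_{hj},
#' \sigma^2_{hj})} and the bulk measurement adds noise with variance
#' \eqn{\tau^2_j}. Because the marginal variance is linear in
#' \eqn{(\sigma^2_{1j},\ldots,\sigma^2_{kj},\tau^2_j)}, the likelihood is
#' maximized per CpG by alternating exact generalized least squares for the
#' mean parameters with a Fisher-scoring step for the variance parameters
#' (a weighted least-squares fit of the squared residuals on the squared
#' proportions), projected onto the variance floor and safeguarded by
#' step-halving backtracking, so the per-iteration log-likelihood trace is
#' non-decreasing by construction. Initialization: \eqn{\mu} from the OLS
#' solve of `X` on `W`, \eqn{\sigma^2} from the per-CpG residual variance
#' split equally across cell types, \eqn{\tau^2} from 10% of the residual
#' variance.
#'
#' @param X `n x m` bulk matrix (samples in rows).
#' @param W `n x k` cell-type proportions, rows on the simplex; `n > 2k`
#'   required.
#' @param covariates optional `n x p` matrix entering the bulk mean
#'   additively.
#' @param tol convergence tolerance on the per-CpG relative change in
#'   log-likelihood (default `1e-6`).
#' @param max_iter maximum iterations (default 200). CpGs that have not met
#'   `tol` by then are flagged in `converged` and the best iterate is
#'   returned, with a warning.
#' @param var_floor lower bound applied to all variance parameters
#'   (default `1e-8`).
#' @param keep_trace logical; retain the per-iteration log-likelihood matrix
#'   (iterations x CpGs) as the `trace` element.
#' @return object of class `tca_params`: list with `mu_hat` (`m x k`),
#'   `sigma2_hat` (`m x k`), `tau2_hat` (length `m`), `delta_hat` (covariate
#'   coefficients or `NULL`), `loglik` (final per-CpG log-likelihood),
#'   `n_iter`, `converged` (logical per CpG) and optionally `trace`.
#' @export
fit_tca <- function(X, W, covariates = NULL, tol = 1e-6, max_iter = 200,
                    var_floor = 1e-8, keep_trace = FALSE) {
  dat <- check_assoc_inputs(X, W, NULL, covariates)
  X <- dat$X; W <- dat$W; C <- dat$C
  n <- nrow(X); m <- ncol(X); k <- ncol(W)
  if (n <= 2 * k)
    stop_param("insufficient samples: need n > 2k (n = %d, k = %d)", n, k)

  # initialization: OLS means, residual variance split across components
  Dm <- cbind(W, C)
  coef0 <- solve(crossprod(Dm), crossprod(Dm, X))      # (k+p) x m
  mu0 <- t(coef0[seq_len(k), , drop = FALSE])          # m x k
  delta0 <- if (!is.null(C)) t(coef0[-seq_len(k), , drop = FALSE])
            else matrix(0, m, 0)
  resvar <- colSums((X - Dm %*% coef0)^2) / n
  sigma20 <- matrix(pmax(0.9 * resvar / k, var_floor), m, k)
  tau20 <- pmax(0.1 * resvar, var_floor)

  fit <- .fit_marginal_cpp(X, W, if (!is.null(C)) C else matrix(0, n, 0),
                     mu0, sigma20, tau20, delta0,
                     tol, as.integer(max_iter), var_floor, keep_trace)
  conv <- as.logical(fit$converged)
  if (!all(conv))
    warning(sprintf("%d of %d CpGs did not reach tol = %g within %d iterations",
                    sum(!conv), m, tol, max_iter))
  mu <- fit$mu; sigma2 <- fit$sigma2; tau2 <- as.vector(fit$tau2)
  loglik <- as.vector(fit$loglik)
  dimnames(mu) <- dimnames(sigma2) <- list(colnames(X), colnames(W))
  names(tau2) <- names(loglik) <- colnames(X)
  structure(list(mu_hat = mu, sigma2_hat = sigma2, tau2_hat = tau2,
                 delta_hat = if (!is.null(C)) fit$delta,
                 loglik = loglik, n_iter = as.integer(max(fit$n_iter)),
                 converged = stats::setNames(conv, colnames(X)),
                 trace = if (keep_trace) fit$trace),
            class = "tca_params")
}

#' @export
print.tca_params <- function(x, ...) {
  cat(sprintf("<tca_params> m=%d CpGs, k=%d cell types; <=%d iterations, %d converged\n",
              nrow(x$mu_hat), ncol(x$mu_hat), x$n_iter, sum(x$converged)))
  invisible(x)
}

#' Cell-type-level X|Y association test under the latent component model
#'
#' Extends the fitted marginal model with a per-cell-type phenotype term
#' \eqn{W_{ih}\beta_{hj} y_i}: per CpG, all `k` effect coefficients are
#' estimated jointly by generalized least squares on the design
#' `[W, W*y, covariates]` with per-sample weights from the fitted marginal
#' variance \eqn{\sum_h W_{ih}^2 \hat\sigma^2_{hj} + \hat\tau^2_j}, and each
#' coefficient gets a two-sided Wald-type test with the covariance rescaled
#' by the Pearson dispersion of the weighted residuals and a t reference
#' with `n - (2k + p)` degrees of freedom (plugged-in weights make the raw
#' model-based Wald z mildly conservative; the dispersion rescaling restores
#' nominal calibration). When the fitted variances are homoscedastic across
#' samples both the estimates and the p-values coincide exactly with
#' [fit_interaction_model()]: the interaction regression is the
#' equal-weights degenerate case of this test.
#'
#' @inheritParams fit_tca
#' @param y length-`n` phenotype.
#' @param params optional pre-fitted [fit_tca()] object for the same
#'   `(X, W, covariates)`; fitted on the fly when `NULL`.
#' @param ... passed on to [fit_tca()] when `params` is `NULL`.
#' @return an `assoc_table` data.frame (see [fit_interaction_model()]);
#'   `statistic` is a dispersion-rescaled Wald t-statistic.
#' @export
tca_test_xgy <- function(X, W, y, covariates = NULL, params = NULL, ...) {
  dat <- check_assoc_inputs(X, W, y, covariates)
  X <- dat$X; W <- dat$W; y <- dat$y; C <- dat$C
  n <- nrow(X); m <- ncol(X); k <- ncol(W)
  if (is.null(params)) params <- fit_tca(X, W, covariates = C, ...)
  stopifnot(inherits(params, "tca_params"))
  if (nrow(params$mu_hat) != m || ncol(params$mu_hat) != k)
    stop_param("`params` dimensions do not match X and W")
  D <- cbind(W, W * y, C)
  if (qr(D)$rank < ncol(D))
    stop_param("singular design%s",
               if (length(unique(y)) < 2) ": `y` is constant" else "")
  if (n <= ncol(D))
    stop_param("insufficient samples: n = %d, design has %d columns",
               n, ncol(D))
  V <- W^2 %*% t(params$sigma2_hat) +
    matrix(params$tau2_hat, n, m, byrow = TRUE)   # n x m fitted variances
  inter <- k + seq_len(k)
  q <- ncol(D)
  est <- se <- matrix(NA_real_, m, k)
  for (j in seq_len(m)) {
    wts <- 1 / sqrt(V[, j])
    Dw <- D * wts
    cov_j <- chol2inv(chol(crossprod(Dw)))
    xw <- X[, j] * wts
    b <- cov_j %*% crossprod(Dw, xw)
    # Pearson dispersion: guards the Wald scale against the finite-sample
    # bias of plugging estimated variances into the GLS weights
    phi <- sum((xw - Dw %*% b)^2) / (n - q)
    est[j, ] <- b[inter]
    se[j, ] <- sqrt(diag(cov_j)[inter] * phi)
  }
  z <- est / se
  pval <- 2 * stats::pt(abs(z), df = n - q, lower.tail = FALSE)
  new_assoc_table(cpgs = colnames(X), cells = colnames(W),
                  estimate = est, std_error = se, statistic = z,
                  p_value = pval)
}

#' Posterior-mean estimate of the cell-type-level methylation tensor
#'
#' Under the fitted Gaussian component model, the latent vector
#' \eqn{Z_{ij\cdot}} and the bulk observation \eqn{X_{ij}} are jointly
#' Gaussian, so the conditional expectation is closed-form:
#' \deqn{\hat Z_{ihj} = \hat\mu_{hj} + \frac{W_{ih}\hat\sigma^2_{hj}}
#'   {\sum_l W_{il}^2\hat\sigma^2_{lj} + \hat\tau^2_j}
#'   \big(X_{ij} - \textstyle\sum_l W_{il}\hat\mu_{lj}\big).}
#' For a Gaussian posterior the mean and the mode coincide.
#'
#' @inheritParams fit_tca
#' @param params a [fit_tca()] fit for the same `(X, W, covariates)`.
#' @return an `n x m x k` array of class `tensor_estimate`.
#' @export
estimate_tensor <- function(X, W, params, covariates = NULL) {
  dat <- check_assoc_inputs(X, W, NULL, covariates)
  X <- dat$X; W <- dat$W; C <- dat$C
  n <- nrow(X); m <- ncol(X); k <- ncol(W)
  stopifnot(inherits(params, "tca_params"))
  if (nrow(params$mu_hat) != m || ncol(params$mu_hat) != k)
    stop_param("`params` dimensions (%d x %d) do not match X (%d CpGs) and W (%d cell types)",
               nrow(params$mu_hat), ncol(params$mu_hat), m, k)
  Mean <- W %*% t(params$mu_hat)
  if (!is.null(C)) {
    if (is.null(params$delta_hat))
      stop_param("covariates supplied but `params` was fitted without them")
    Mean <- Mean + C %*% t(params$delta_hat)
  }
  R <- X - Mean
  DEN <- W^2 %*% t(params$sigma2_hat) +
    matrix(params$tau2_hat, n, m, byrow = TRUE)
  RD <- R / DEN
  Z_hat <- array(NA_real_, dim = c(n, m, k),
                 dimnames = list(rownames(X), colnames(X), colnames(W)))
  for (h in seq_len(k)) {
    Z_hat[, , h] <- matrix(params$mu_hat[, h], n, m, byrow = TRUE) +
      (W[, h] %o% params$sigma2_hat[, h]) * RD
  }
  class(Z_hat) <- c("tensor_estimate", class(Z_hat))
  Z_hat
}

#' Y|X association test: phenotype regressed on estimated tensor
#'
#' The reverse-direction test of the latent component model: for every
#' (CpG, cell type) pair, the phenotype is tested for association with the
#' posterior-mean cell-type-level methylation from [estimate_tensor()]. For
#' a binary phenotype the test is the Rao score test of adding the tensor
#' column to a logistic regression of `y` on the covariates (intercept-only
#' under no covariates); the score test needs no per-pair model fit, is
#' immune to complete separation, and its statistic is standard normal under
#' the null. For a continuous phenotype the analogous linear-model score
#' test is used. The reported `estimate` is the one-step (score/information)
#' coefficient update from zero.
#'
#' @param Z_hat `n x m x k` tensor from [estimate_tensor()].
#' @param y length-`n` phenotype; binary 0/1 (logistic score test) or
#'   continuous (linear score test).
#' @param covariates optional `n x p` matrix adjusted for in the null model.
#' @param joint logical; if `TRUE`, fit one logistic (or linear) model per
#'   CpG with all `k` tensor columns jointly and report per-coefficient Wald
#'   tests. The joint fit partials the shared bulk residual out of each
#'   cell type's coefficient, which removes cross-cell-type leakage but --
#'   because the tensor columns within a CpG are nearly collinear -- at a
#'   severe cost in power. Default `FALSE` (marginal tests, one cell type
#'   at a time).
#' @return an `assoc_table` data.frame. Pairs with a (covariate-adjusted)
#'   constant tensor column carry no information and are reported with
#'   `statistic = 0`, `p_value = 1`.
#' @export
tca_test_ygx <- function(Z_hat, y, covariates = NULL, joint = FALSE) {
  if (length(dim(Z_hat)) != 3L)
    stop_param("`Z_hat` must be an n x m x k array")
  n <- dim(Z_hat)[1]; m <- dim(Z_hat)[2]; k <- dim(Z_hat)[3]
  if (length(y) != n)
    stop_param("y has length %d but Z_hat has %d samples", length(y), n)
  y <- as.numeric(y)
  binary <- all(y %in% c(0, 1))
  C <- if (!is.null(covariates)) as.matrix(covariates)
  if (!is.null(C) && nrow(C) != n)
    stop_param("covariates have %d rows but Z_hat has %d samples", nrow(C), n)
  Dn <- cbind(`(Intercept)` = rep(1, n), C)
  if (joint) return(tca_test_ygx_joint(Z_hat, y, Dn, binary))

  if (binary) {
    if (length(unique(y)) < 2)
      stop_param("`y` is constant")
    fit0 <- stats::glm.fit(Dn, y, family = stats::binomial())
    phat <- fit0$fitted.values
    v <- phat * (1 - phat)
    yres <- y - phat
  } else {
    fit0 <- stats::lm.fit(Dn, y)
    yres <- fit0$residuals
    s2 <- sum(yres^2) / max(1, n - ncol(Dn))
    v <- rep(s2, n)
    # score residual scale: for the linear model U = sum(yres * z)/s2,
    # I = sum(v * ztilde^2)/s2^2; the s2 factors cancel in U/sqrt(I) if we
    # use v = s2 below, matching the logistic branch algebraically.
  }
  # v-weighted projection of tensor columns onto the null design
  DtVD_inv <- solve(crossprod(Dn, Dn * v))
  cpgs <- dimnames(Z_hat)[[2]] %||% cpg_ids(m)
  cells <- dimnames(Z_hat)[[3]] %||% celltype_ids(k)
  est <- se <- stat <- matrix(NA_real_, m, k)
  for (h in seq_len(k)) {
    Zh <- Z_hat[, , h, drop = TRUE]
    if (is.null(dim(Zh))) Zh <- matrix(Zh, n, m)
    Zt <- Zh - Dn %*% (DtVD_inv %*% crossprod(Dn, Zh * v))
    U <- as.vector(crossprod(yres, Zh))
    Vh <- colSums(Zt^2 * v)
    # the statistic is scale-invariant in the tensor column, so arbitrarily
    # small (but nonzero) posterior variation is still informative; only an
    # exactly constant adjusted column carries no information
    ok <- Vh > 0
    st <- ifelse(ok, U / sqrt(pmax(Vh, .Machine$double.xmin)), 0)
    est[, h] <- ifelse(ok, U / pmax(Vh, .Machine$double.xmin), 0)
    se[, h] <- ifelse(ok, 1 / sqrt(Vh), NA_real_)
    stat[, h] <- st
  }
  pval <- 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  new_assoc_table(cpgs = cpgs, cells = cells, estimate = est,
                  std_error = se, statistic = stat, p_value = pval)
}

# per-CpG joint model: all k tensor columns enter one regression
tca_test_ygx_joint <- function(Z_hat, y, Dn, binary) {
  n <- dim(Z_hat)[1]; m <- dim(Z_hat)[2]; k <- dim(Z_hat)[3]
  cpgs <- dimnames(Z_hat)[[2]] %||% cpg_ids(m)
  cells <- dimnames(Z_hat)[[3]] %||% celltype_ids(k)
  est <- se <- stat <- matrix(NA_real_, m, k)
  sel <- ncol(Dn) + seq_len(k)
  for (j in seq_len(m)) {
    D <- cbind(Dn, matrix(Z_hat[, j, ], n, k))
    ok <- qr(D)$rank == ncol(D)
    if (!ok) next
    if (binary) {
      f <- tryCatch(suppressWarnings(
        stats::glm.fit(D, y, family = stats::binomial())),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) next
      v <- f$fitted.values * (1 - f$fitted.values)
      cv <- tryCatch(solve(crossprod(D, D * v)), error = function(e) NULL)
      if (is.null(cv)) next
      est[j, ] <- f$coefficients[sel]
      se[j, ] <- sqrt(diag(cv)[sel])
    } else {
      f <- stats::lm.fit(D, y)
      s2 <- sum(f$residuals^2) / (n - ncol(D))
      cv <- chol2inv(chol(crossprod(D))) * s2
      est[j, ] <- f$coefficients[sel]
      se[j, ] <- sqrt(diag(cv)[sel])
    }
    stat[j, ] <- est[j, ] / se[j, ]
  }
  pval <- 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  pval[is.na(pval)] <- 1
  stat[is.na(stat)] <- 0
  new_assoc_table(cpgs = cpgs, cells = cells, estimate = est,
                  std_error = se, statistic = stat, p_value = pval)
}
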