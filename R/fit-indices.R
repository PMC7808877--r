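# Fit indices for ML/FIML factor models.

# chi2 / df of target model, chi2_b / df_b of the independence baseline,
# n cases, saturated covariance s and model-implied covariance sigma.
fit_index_values <- function(chi2, df, chi2_b, df_b, n, s, sigma) {
  d_m <- max(chi2 - df, 0)
  d_b <- max(chi2_b - df_b, 0)
  cfi <- if (max(d_m, d_b) == 0) 1 else 1 - d_m / max(d_m, d_b)
  tli <- if (df == 0 || df_b == 0 || chi2_b / df_b <= 1) {
    if (df == 0) NA_real_ else ((chi2_b / df_b) - (chi2 / df)) / max(chi2_b / df_b - 1, .Machine$double.eps)
  } else {
    ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
  }
  if (df == 0) {
    rmsea <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else {
    rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
    ci <- rmsea_ci(chi2, df, n)
    lo <- ci[1L]; hi <- ci[2L]
  }
  # SRMR over the p(p+1)/2 nonredundant covariance moments, standardized by
  # the saturated variances
  dsd <- sqrt(diag(s))
  res <- (s - sigma) / tcrossprod(dsd)
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  list(cfi = cfi, tli = tli, rmsea = rmsea,
       rmsea_ci_lower = lo, rmsea_ci_upper = hi, srmr = srmr)
}

# 90% confidence interval for RMSEA by inverting the noncentral chi-square
# distribution of the test statistic.
rmsea_ci <- function(chi2, df, n, level = 0.90) {
  alpha <- (1 - level) / 2
  ncp_root <- function(target) {
    f <- function(ncp) stats::pchisq(chi2, df, ncp = ncp) - target
    if (f(0) < 0) return(NA_real_)
    hi <- max(chi2 * 2, df * 2, 10)
    while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
    if (f(hi) > 0) return(NA_real_)
    stats::uniroot(f, c(0, hi), tol = 1e-9)$root
  }
  # lower bound: ncp with P(X <= chi2) = 1 - alpha; upper: = alpha
  lo_ncp <- if (stats::pchisq(chi2, df) < 1 - alpha) 0 else ncp_root(1 - alpha)
  hi_ncp <- if (stats::pchisq(chi2, df) < alpha) 0 else ncp_root(alpha)
  to_rmsea <- function(ncp) if (is.na(ncp)) NA_real_ else sqrt(max(ncp, 0) / (df * (n - 1)))
  c(to_rmsea(lo_ncp), to_rmsea(hi_ncp))
}

#' Apply the conjunction good-fit rule to a fitted model
#'
#' A model is judged good-fitting when CFI >= .95, TLI >= .95, RMSEA <= .08
#' and SRMR <= .08 all hold (boundary values count as passing). A model that
#' did not converge, is inadmissible (Heywood case), or has an undefined
#' index (e.g. a saturated model, where TLI and RMSEA do not exist) is never
#' judged good.
#'
#' @param fit A `cfa_fit` object.
#' @param cutoffs Named list of thresholds (`cfi`, `tli`, `rmsea`, `srmr`).
#' @return Logical scalar.
#' @export
good_fit <- function(fit, cutoffs = list(cfi = 0.95, tli = 0.95,
                                         rmsea = 0.08, srmr = 0.08)) {
  stopifnot(inherits(fit, "cfa_fit"))
  vals <- c(fit$cfi, fit$tli, fit$rmsea, fit$srmr)
  if (any(is.na(vals))) return(FALSE)
  isTRUE(fit$converged) && isTRUE(fit$admissible) &&
    fit$cfi >= cutoffs$cfi && fit$tli >= cutoffs$tli &&
    fit$rmsea <= cutoffs$rmsea && fit$srmr <= cutoffs$srmr
}

#' One-row fit-index summary of a fitted model
#'
#' @param fit A `cfa_fit` object.
#' @param model Label for the model column.
#' @return A one-row data frame in the layout of a fit-index table
#'   (chi-square, df, p, CFI, TLI, RMSEA with CI, SRMR, AIC, BIC, verdict).
#' @export
fit_summary_row <- function(fit, model = "model") {
  data.frame(model = model, chi2 = fit$chi2, df = fit$df, p = fit$p_value,
             cfi = fit$cfi, tli = fit$tli, rmsea = fit$rmsea,
             rmsea_ci_lower = fit$rmsea_ci_lower,
             rmsea_ci_upper = fit$rmsea_ci_upper,
             srmr = fit$srmr, aic = fit$aic, bic = fit$bic,
             n = fit$n_used, converged = fit$converged,
             admissible = fit$admissible, good = good_fit(fit),
             stringsAsFactors = FALSE)
}
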