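# Heterogeneity, pleiotropy and influence diagnostics for one
# exposure-outcome instrument set.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (beta_out_j - fitted_j)^2)` with `w_j = 1/se_out_j^2` and
#' fitted values from the stated model: the IVW fit through the origin
#' (df = J - 1) or the MR-Egger fit with intercept (Q', df = J - 2). The
#' p-value is from the chi-square distribution with the stated df; large Q
#' relative to df indicates heterogeneity among the per-SNP estimates.
#'
#' @param h a [harmonized_set].
#' @param model `"ivw"` (J >= 2) or `"egger"` (J >= 3).
#' @return list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(h, model = c("ivw", "egger")) {
  model <- match.arg(model)
  stopifnot(inherits(h, "harmonized_set"))
  j <- n_snps(h)
  if (model == "ivw") {
    if (j < 2) abort(sprintf("Cochran Q (IVW) needs J >= 2, got %d", j),
                     "mrmediate_insufficient_snps")
    q <- ivw_core(h$data$beta_exp, h$data$beta_out, h$data$se_out)$q
    df <- j - 1
  } else {
    if (j < 3) abort(sprintf("Cochran Q' (Egger) needs J >= 3, got %d", j),
                     "mrmediate_insufficient_snps")
    q <- attr(mr_egger(h), "Q")
    df <- j - 2
  }
  list(Q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' A nonzero Egger intercept estimates average directional pleiotropy;
#' horizontal pleiotropy is flagged when the intercept p-value is below
#' `alpha`.
#'
#' @param h a [harmonized_set] with J >= 3.
#' @param alpha flag threshold, default 0.05.
#' @return list with `estimate`, `se`, `pval`, `pleiotropy` (logical flag).
#' @export
egger_intercept_test <- function(h, alpha = 0.05) {
  egger <- mr_egger(h)
  c(egger$intercept, list(pleiotropy = egger$intercept$pval < alpha))
}

#' Leave-one-out IVW series
#'
#' Re-estimates the IVW effect J times, each time excluding one instrument.
#' Each entry is identical to a fresh [mr_ivw()] call on that subset.
#'
#' @param h a [harmonized_set] with J >= 3.
#' @param variant IVW variant used for every subset fit.
#' @return data.frame with one row per left-out SNP: `left_out_snp`,
#'   `estimate`, `se`, `pval`, `n_snp`.
#' @export
leave_one_out <- function(h, variant = c("mre", "fixed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(h, "harmonized_set"))
  j <- n_snps(h)
  if (j < 3) abort(sprintf("leave-one-out needs J >= 3, got %d", j),
                   "mrmediate_insufficient_snps")
  rows <- lapply(seq_len(j), function(i) {
    sub <- h
    sub$data <- h$data[-i, , drop = FALSE]
    fit <- mr_ivw(sub, variant)
    data.frame(left_out_snp = h$data$snp_id[i], estimate = fit$estimate,
               se = fit$se, pval = fit$pval, n_snp = fit$n_snp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles IVW and Egger Cochran Q, the Egger intercept test and the
#' leave-one-out series.
#'
#' @param h a [harmonized_set] with J >= 3.
#' @param alpha pleiotropy/heterogeneity flag threshold.
#' @param ivw_variant IVW variant used for the leave-one-out series.
#' @return An object of class `sensitivity_report`: list with `exposure_id`,
#'   `outcome_id`, `n_snp`, `q_ivw`, `q_egger`, `egger_intercept`, `loo`,
#'   `ivw_variant`.
#' @export
sensitivity_report <- function(h, alpha = 0.05, ivw_variant = c("mre", "fixed")) {
  ivw_variant <- match.arg(ivw_variant)
  structure(
    list(
      exposure_id = h$exposure_id,
      outcome_id = h$outcome_id,
      n_snp = n_snps(h),
      q_ivw = cochran_q(h, "ivw"),
      q_egger = cochran_q(h, "egger"),
      egger_intercept = egger_intercept_test(h, alpha),
      loo = leave_one_out(h, ivw_variant),
      ivw_variant = ivw_variant
    ),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %s -> %s (J = %d, IVW %s)\n",
              x$exposure_id, x$outcome_id, x$n_snp, x$ivw_variant))
  cat(sprintf("  Q (IVW):   %.3f on %d df, p = %.3g\n", x$q_ivw$Q, x$q_ivw$df, x$q_ivw$pval))
  cat(sprintf("  Q' (Egger): %.3f on %d df, p = %.3g\n", x$q_egger$Q, x$q_egger$df, x$q_egger$pval))
  cat(sprintf("  Egger intercept: %.4g (se %.4g, p = %.3g)%s\n",
              x$egger_intercept$estimate, x$egger_intercept$se, x$egger_intercept$pval,
              if (x$egger_intercept$pleiotropy) " [pleiotropy flagged]" else ""))
  cat(sprintf("  leave-one-out: %d refits, estimate range %.4g..%.4g\n",
              nrow(x$loo), min(x$loo$estimate), max(x$loo$estimate)))
  invisible(x)
}
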