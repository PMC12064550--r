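# Multi-exposure screening cascade (significance, OR-direction consistency,
# pleiotropy and heterogeneity gates, optional reverse-direction check) and
# the two-step product-of-coefficients mediation decomposition.

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with enforced monotonicity (delegates to
#' `stats::p.adjust(method = "BH")` after range validation).
#'
#' @param pvals numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values (`adjusted >= raw`, `adjusted <= 1`).
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1]", "mrmediate_bad_input")
  }
  stats::p.adjust(pvals, method = "BH")
}

REQUIRED_METHODS <- c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode")

#' Screen total-effect results across exposures
#'
#' Applies, per exposure, the gates used to call a phenotype a risk or
#' protective factor: IVW significance (nominal p or FDR-adjusted p,
#' controlled by `screen_on`), effect-direction consistency across all five
#' methods (all odds ratios above 1 or all below 1, i.e. all estimates share
#' a sign), Egger-intercept p-value above `alpha` (no directional
#' pleiotropy), and IVW Cochran-Q p-value above `alpha` (no heterogeneity).
#' The FDR-adjusted IVW p-value is always reported alongside. A reverse-MR
#' p-value, when supplied, is recorded descriptively as `reverse_ok`
#' (`"yes"`, `"no"`, or `"untestable"`) and does not gate the verdict.
#'
#' @param pair_results named list, one element per exposure, each a list with
#'   `results` (the data.frame from [mr_all_methods()]) and `sensitivity`
#'   (a [sensitivity_report()]); optional `reverse_pval` (NA = untestable).
#' @param alpha significance level for all gates, default 0.05.
#' @param screen_on `"nominal"` (gate on the raw IVW p) or `"fdr"` (gate on
#'   the BH-adjusted p).
#' @return data.frame with one `ScreenRecord` row per exposure: `exposure_id`,
#'   `ivw_estimate`, `ivw_pval`, `fdr_pval`, `direction_consistent`,
#'   `pleiotropy_ok`, `heterogeneity_ok`, `reverse_ok`, `verdict`
#'   (`"risk"`/`"protective"`/`"excluded"`), `reason`.
#' @export
screen_total_effects <- function(pair_results, alpha = 0.05,
                                 screen_on = c("nominal", "fdr")) {
  screen_on <- match.arg(screen_on)
  ids <- names(pair_results)
  if (is.null(ids)) abort("pair_results must be a named list", "mrmediate_bad_input")

  extract <- function(id) {
    pr <- pair_results[[id]]
    res <- pr$results
    missing_methods <- setdiff(REQUIRED_METHODS, res$method)
    if (length(missing_methods) > 0) {
      abort(sprintf("exposure '%s' lacks method result(s): %s",
                    id, paste(missing_methods, collapse = ", ")),
            "mrmediate_missing_methods")
    }
    ivw <- res[res$method == "ivw", ]
    ests <- res$estimate[match(REQUIRED_METHODS, res$method)]
    list(
      ivw_estimate = ivw$estimate,
      ivw_pval = ivw$pval,
      direction = all(ests > 0) || all(ests < 0),
      intercept_pval = pr$sensitivity$egger_intercept$pval,
      q_pval = pr$sensitivity$q_ivw$pval,
      reverse_pval = pr$reverse_pval %||% NA_real_
    )
  }

  rows <- lapply(ids, function(id) {
    tryCatch(list(ok = TRUE, val = extract(id)),
             mrmediate_missing_methods = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  })
  names(rows) <- ids

  ok_ids <- ids[vapply(rows, `[[`, logical(1), "ok")]
  ivw_p <- vapply(rows[ok_ids], function(r) r$val$ivw_pval, numeric(1))
  fdr_p <- bh_fdr(ivw_p)
  names(fdr_p) <- ok_ids

  out <- lapply(ids, function(id) {
    r <- rows[[id]]
    if (!r$ok) {
      return(data.frame(
        exposure_id = id, ivw_estimate = NA_real_, ivw_pval = NA_real_,
        fdr_pval = NA_real_, direction_consistent = NA, pleiotropy_ok = NA,
        heterogeneity_ok = NA, reverse_ok = NA_character_,
        verdict = "excluded", reason = r$msg, stringsAsFactors = FALSE
      ))
    }
    v <- r$val
    sig_p <- if (screen_on == "nominal") v$ivw_pval else fdr_p[[id]]
    significant <- sig_p < alpha
    pleio_ok <- v$intercept_pval > alpha
    het_ok <- v$q_pval > alpha
    reverse_ok <- if (is.na(v$reverse_pval)) "untestable" else
      if (v$reverse_pval >= alpha) "yes" else "no"
    gates <- c(significance = significant, direction = v$direction,
               pleiotropy = pleio_ok, heterogeneity = het_ok)
    verdict <- if (all(gates)) {
      if (v$ivw_estimate > 0) "risk" else "protective"
    } else "excluded"
    data.frame(
      exposure_id = id, ivw_estimate = v$ivw_estimate, ivw_pval = v$ivw_pval,
      fdr_pval = unname(fdr_p[[id]]), direction_consistent = v$direction,
      pleiotropy_ok = pleio_ok, heterogeneity_ok = het_ok,
      reverse_ok = reverse_ok, verdict = verdict,
      reason = if (all(gates)) "" else paste(names(gates)[!gates], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-step mediation decomposition (product of coefficients)
#'
#' Given three independently estimated effects — exposure on mediator
#' (`beta1`), mediator on outcome (`beta2`) and exposure on outcome
#' (`total`) — computes the mediated effect `me = beta1 * beta2` with the
#' Sobel (delta-method) SE `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`, the direct
#' effect `total - me`, and the mediated proportion `mp = me/total` reported
#' in percent with a first-order ratio delta SE. Covariances are zero because
#' the three legs come from non-overlapping samples. All quantities are
#' signed; no clamping is applied.
#'
#' @param beta1,beta2,total [mr_result] objects (or lists with `estimate`
#'   and `se`).
#' @param exposure_id,mediator_id,outcome_id optional identifiers carried
#'   into the result.
#' @return An object of class `mediation_result`: list with `beta1`, `se1`,
#'   `beta2`, `se2`, `total`, `total_se`, `me`, `me_se`, `me_pval`, `direct`,
#'   `mp_pct`, `mp_se_pct` and the identifiers.
#' @export
two_step_mediation <- function(beta1, beta2, total,
                               exposure_id = NA_character_,
                               mediator_id = NA_character_,
                               outcome_id = NA_character_) {
  b1 <- beta1$estimate; s1 <- beta1$se
  b2 <- beta2$estimate; s2 <- beta2$se
  bt <- total$estimate; st <- total$se
  if (is.null(bt) || !is.finite(bt) || bt == 0) {
    abort("mediated proportion undefined: total effect is zero", "mrmediate_undefined_proportion")
  }
  me <- b1 * b2
  me_se <- sqrt(b1^2 * s2^2 + b2^2 * s1^2)
  mp <- me / bt
  # first-order delta for a ratio of independent estimates
  mp_var <- me_se^2 / bt^2 + me^2 * st^2 / bt^4
  direct <- bt - me
  structure(
    list(
      exposure_id = exposure_id, mediator_id = mediator_id, outcome_id = outcome_id,
      beta1 = b1, se1 = s1, beta2 = b2, se2 = s2,
      total = bt, total_se = st,
      me = me, me_se = me_se,
      me_pval = if (me_se > 0) two_sided_p(me / me_se) else if (me == 0) 1 else .Machine$double.xmin,
      direct = direct, direct_se = sqrt(st^2 + me_se^2),
      mp_pct = 100 * mp, mp_se_pct = 100 * sqrt(mp_var)
    ),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s\n", x$exposure_id, x$mediator_id, x$outcome_id))
  cat(sprintf("  beta1 %.4g (se %.4g); beta2 %.4g (se %.4g)\n", x$beta1, x$se1, x$beta2, x$se2))
  cat(sprintf("  total %.4g, mediated %.4g (se %.4g), direct %.4g\n",
              x$total, x$me, x$me_se, x$direct))
  cat(sprintf("  mediated proportion %.3g%% (se %.3g)\n", x$mp_pct, x$mp_se_pct))
  invisible(x)
}

#' Assemble exposure-mediator pairs and decompose their effects
#'
#' A pair (X, M) enters when X passed the total-effect screen (verdict not
#' `"excluded"`), the mediator-outcome IVW p-value is below `alpha`, and the
#' exposure-mediator IVW p-value is below `alpha`; each surviving pair is
#' decomposed with [two_step_mediation()]. The `meaningful` flag applies a
#' swappable predicate on the two path p-values (default: both below
#' `alpha`). The entry gates can be relaxed (`require_mediator`,
#' `require_path`) to inspect non-significant paths; the flag then separates
#' meaningful pairs.
#'
#' @param screen_records output of [screen_total_effects()].
#' @param total_results data.frame of exposure-outcome IVW results:
#'   `exposure_id`, `estimate`, `se`, `pval`.
#' @param exp_med_results data.frame of exposure-mediator IVW results:
#'   `exposure_id`, `mediator_id`, `estimate`, `se`, `pval`.
#' @param med_out_results data.frame of mediator-outcome IVW results:
#'   `mediator_id`, `estimate`, `se`, `pval`.
#' @param alpha path significance level, default 0.05.
#' @param outcome_id identifier carried into results.
#' @param meaningful predicate `function(p1, p2, alpha)` flagging a pair.
#' @param require_mediator,require_path entry gates (default TRUE).
#' @return data.frame with one row per assembled pair, containing both path
#'   estimates, the decomposition (`me`, `me_se`, `direct`, `mp_pct`,
#'   `mp_se_pct`) and the `meaningful` flag. Zero rows is a valid result.
#' @export
assemble_pairs <- function(screen_records, total_results, exp_med_results,
                           med_out_results, alpha = 0.05,
                           outcome_id = NA_character_,
                           meaningful = function(p1, p2, alpha) p1 < alpha & p2 < alpha,
                           require_mediator = TRUE, require_path = TRUE) {
  screened <- screen_records$exposure_id[screen_records$verdict != "excluded"]
  sig_med <- if (require_mediator) {
    med_out_results$mediator_id[med_out_results$pval < alpha]
  } else {
    med_out_results$mediator_id
  }
  cand <- exp_med_results[exp_med_results$exposure_id %in% screened &
                            exp_med_results$mediator_id %in% sig_med, , drop = FALSE]
  if (require_path) cand <- cand[cand$pval < alpha, , drop = FALSE]

  empty <- data.frame(
    exposure_id = character(), mediator_id = character(), outcome_id = character(),
    beta1 = numeric(), se1 = numeric(), p1 = numeric(),
    beta2 = numeric(), se2 = numeric(), p2 = numeric(),
    total = numeric(), total_se = numeric(),
    me = numeric(), me_se = numeric(), direct = numeric(),
    mp_pct = numeric(), mp_se_pct = numeric(), meaningful = logical(),
    stringsAsFactors = FALSE
  )
  if (nrow(cand) == 0) return(empty)

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    x <- cand$exposure_id[i]
    m <- cand$mediator_id[i]
    mo <- med_out_results[med_out_results$mediator_id == m, ][1, ]
    tot <- total_results[total_results$exposure_id == x, ][1, ]
    dec <- two_step_mediation(
      beta1 = list(estimate = cand$estimate[i], se = cand$se[i]),
      beta2 = list(estimate = mo$estimate, se = mo$se),
      total = list(estimate = tot$estimate, se = tot$se),
      exposure_id = x, mediator_id = m, outcome_id = outcome_id
    )
    data.frame(
      exposure_id = x, mediator_id = m, outcome_id = outcome_id,
      beta1 = dec$beta1, se1 = dec$se1, p1 = cand$pval[i],
      beta2 = dec$beta2, se2 = dec$se2, p2 = mo$pval,
      total = dec$total, total_se = dec$total_se,
      me = dec$me, me_se = dec$me_se, direct = dec$direct,
      mp_pct = dec$mp_pct, mp_se_pct = dec$mp_se_pct,
      meaningful = meaningful(cand$pval[i], mo$pval, alpha),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
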