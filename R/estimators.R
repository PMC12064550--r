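# Causal-effect estimators on a harmonized instrument set. All methods are
# built on the per-SNP Wald ratio; inverse-variance weighting uses 1/se_out^2
# throughout, matching the standard second-order-ignored convention.

MR_METHODS <- c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode", "wald")

#' Assemble a single MR estimate
#'
#' @param method one of `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"simple_mode"`, `"weighted_mode"`, `"wald"`.
#' @param estimate causal effect per unit exposure (log-OR scale for a binary
#'   outcome).
#' @param se standard error (> 0 except in exact-fit degeneracies).
#' @param n_snp number of instruments used.
#' @param df if non-NULL, p-value and CI use a t reference with `df` degrees
#'   of freedom; otherwise standard normal.
#' @param outcome_binary when TRUE, `or_point`/`or_low`/`or_high` are the
#'   exponentiated effect and interval.
#' @return An object of class `mr_result` (named list).
#' @export
mr_result <- function(method, estimate, se, n_snp, df = NULL, outcome_binary = FALSE) {
  method <- match.arg(method, MR_METHODS)
  crit <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df)
  ci_low <- estimate - crit * se
  ci_high <- estimate + crit * se
  z <- if (se > 0) estimate / se else sign(estimate) * Inf
  pval <- if (is.null(df)) two_sided_p(z) else max(2 * stats::pt(-abs(z), df), .Machine$double.xmin)
  res <- list(
    method = method, estimate = estimate, se = se,
    ci_low = ci_low, ci_high = ci_high, pval = pval, n_snp = n_snp,
    or_point = if (outcome_binary) exp(estimate) else NA_real_,
    or_low = if (outcome_binary) exp(ci_low) else NA_real_,
    or_high = if (outcome_binary) exp(ci_high) else NA_real_
  )
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: %.4g (se %.4g, 95%% CI %.4g..%.4g, p = %.3g, J = %d)\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pval, x$n_snp))
  invisible(x)
}

#' Per-SNP Wald ratio
#'
#' @param beta_exp,se_exp SNP-exposure effect and SE.
#' @param beta_out,se_out SNP-outcome effect and SE.
#' @return list with `ratio = beta_out/beta_exp` and the first-order
#'   delta-method `se = se_out/|beta_exp|`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) abort("Wald ratio undefined for beta_exp = 0", "mrmediate_bad_input")
  list(ratio = beta_out / beta_exp, se = se_out / abs(beta_exp))
}

#' @keywords internal
ivw_core <- function(bx, by, sy) {
  w <- 1 / sy^2
  denom <- sum(w * bx^2)
  est <- sum(w * bx * by) / denom
  se_fixed <- sqrt(1 / denom)
  q <- sum(w * (by - est * bx)^2)
  list(estimate = est, se_fixed = se_fixed, q = q)
}

#' Inverse-variance weighted estimator
#'
#' Weighted least squares of `beta_out` on `beta_exp` through the origin with
#' weights `1/se_out^2` — the precision-weighted average of the Wald ratios.
#' The `"mre"` variant (multiplicative random effects, the default) scales
#' the fixed-effects SE by `max(1, sqrt(Q/(J-1)))` so the SE never drops
#' below the fixed-effects one; `"fixed"` reports the analytic SE. P-values
#' use the standard normal.
#'
#' @param h a [harmonized_set].
#' @param variant `"mre"` (needs J >= 2) or `"fixed"` (J >= 1).
#' @return An [mr_result] with the Cochran Q attached as `attr(, "Q")`.
#' @export
mr_ivw <- function(h, variant = c("mre", "fixed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(h, "harmonized_set"))
  j <- n_snps(h)
  min_j <- if (variant == "mre") 2L else 1L
  if (j < min_j) {
    abort(sprintf("IVW (%s) needs at least %d instrument(s), got %d", variant, min_j, j),
          "mrmediate_insufficient_snps")
  }
  core <- ivw_core(h$data$beta_exp, h$data$beta_out, h$data$se_out)
  se <- if (variant == "mre") {
    core$se_fixed * max(1, sqrt(core$q / (j - 1)))
  } else {
    core$se_fixed
  }
  res <- mr_result("ivw", core$estimate, se, j,
                   outcome_binary = h$outcome_type == "binary")
  attr(res, "Q") <- core$q
  attr(res, "variant") <- variant
  res
}

#' MR-Egger regression
#'
#' Rows are oriented so every `beta_exp >= 0` (row signs flipped as needed),
#' then `beta_out` is regressed on `beta_exp` with an intercept, weights
#' `1/se_out^2`. The slope is the pleiotropy-adjusted causal estimate; the
#' intercept estimates average directional pleiotropy. Coefficient SEs scale
#' with the residual dispersion `sqrt(Q'/(J-2))` and p-values use a t
#' reference with J-2 df, the exact small-sample calibration of the weighted
#' linear model.
#'
#' @param h a [harmonized_set] with J >= 3.
#' @return list with elements `slope` (an [mr_result]) and `intercept`
#'   (list of `estimate`, `se`, `pval`); the Egger Q' is in `attr(, "Q")`.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  j <- n_snps(h)
  if (j < 3) abort(sprintf("MR-Egger needs at least 3 instruments, got %d", j),
                   "mrmediate_insufficient_snps")
  sgn <- ifelse(h$data$beta_exp < 0, -1, 1)
  bx <- abs(h$data$beta_exp)
  by <- sgn * h$data$beta_out
  w <- 1 / h$data$se_out^2

  x <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(x, w * x)
  xtwy <- crossprod(x, w * by)
  xtwx_inv <- solve(xtwx)
  coefs <- drop(xtwx_inv %*% xtwy)
  resid <- by - drop(x %*% coefs)
  q_egger <- sum(w * resid^2)
  sigma2 <- q_egger / (j - 2)
  ses <- sqrt(diag(xtwx_inv) * sigma2)

  slope <- mr_result("egger", unname(coefs["slope"]), unname(ses["slope"]), j,
                     df = j - 2, outcome_binary = h$outcome_type == "binary")
  z_int <- if (ses["intercept"] > 0) coefs["intercept"] / ses["intercept"] else
    sign(coefs["intercept"]) * Inf
  intercept <- list(
    estimate = unname(coefs["intercept"]),
    se = unname(ses["intercept"]),
    pval = max(2 * stats::pt(-abs(z_int), j - 2), .Machine$double.xmin)
  )
  out <- list(slope = slope, intercept = intercept)
  attr(out, "Q") <- q_egger
  out
}

#' @keywords internal
weighted_median_core <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' @keywords internal
parametric_bootstrap_se <- function(h, estimator, n_boot, seed) {
  bx <- h$data$beta_exp
  by <- h$data$beta_out
  sx <- h$data$se_exp
  sy <- h$data$se_out
  j <- length(bx)
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      bxb <- stats::rnorm(j, bx, sx)
      byb <- stats::rnorm(j, by, sy)
      bxb[bxb == 0] <- .Machine$double.eps  # ratio guard, probability-zero event
      estimator(bxb, byb, sy)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted median estimator
#'
#' Per-SNP Wald ratios are sorted; with normalized inverse-variance weights
#' `w_j = 1/se_ratio_j^2`, the estimate is the ratio at cumulative midpoint
#' mass 0.5 by linear interpolation of `p_j = sum(w_(1..j)) - w_j/2`. It is
#' consistent when instruments carrying at least half the weight are valid.
#' The SE comes from a parametric bootstrap (betas resampled from their
#' observed normal sampling distributions).
#'
#' @param h a [harmonized_set] with J >= 3.
#' @param n_boot bootstrap replicates for the SE, default 1000.
#' @param seed RNG seed for the bootstrap (the caller's RNG state is
#'   preserved).
#' @return An [mr_result].
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(h, "harmonized_set"))
  j <- n_snps(h)
  if (j < 3) abort(sprintf("weighted median needs at least 3 instruments, got %d", j),
                   "mrmediate_insufficient_snps")
  wr <- wald_ratio(h$data$beta_exp, h$data$se_exp, h$data$beta_out, h$data$se_out)
  est <- weighted_median_core(wr$ratio, 1 / wr$se^2)
  se <- parametric_bootstrap_se(h, function(bx, by, sy) {
    weighted_median_core(by / bx, (abs(bx) / sy)^2)
  }, n_boot, seed)
  mr_result("weighted_median", est, se, j,
            outcome_binary = h$outcome_type == "binary")
}

#' @keywords internal
mode_core <- function(ratios, weights, phi) {
  w <- weights / sum(weights)
  s <- stats::sd(ratios)
  m <- stats::mad(ratios)  # already scaled by 1.4826 = 1/0.6745
  bw <- phi * 0.9 * min(s, m) * length(ratios)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) {
    # degenerate spread: return the ratio value carrying the most weight
    agg <- tapply(w, ratios, sum)
    return(as.numeric(names(agg)[which.max(agg)]))
  }
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw, length.out = 512)
  dens <- drop(exp(-0.5 * (outer(grid, ratios, "-") / bw)^2) %*% w)
  grid[which.max(dens)]
}

#' Mode-based estimator (simple and weighted)
#'
#' Kernel-smoothed density of the per-SNP Wald ratios (normal kernel,
#' bandwidth `phi * 0.9 * min(sd, mad) * J^(-1/5)` with the MAD on the
#' normal-consistent scale); the estimate is the density argmax over a
#' 512-point grid spanning the ratio range plus three bandwidths. Weights are
#' uniform for the simple mode and `1/se_ratio^2` for the weighted mode. SE
#' by parametric bootstrap.
#'
#' @param h a [harmonized_set] with J >= 3.
#' @param weighted use inverse-variance weights (weighted mode) instead of
#'   uniform weights (simple mode).
#' @param phi bandwidth inflation factor, default 1.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed RNG seed for the bootstrap.
#' @return An [mr_result] with method `"simple_mode"` or `"weighted_mode"`.
#' @export
mr_mode <- function(h, weighted = FALSE, phi = 1, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(h, "harmonized_set"))
  j <- n_snps(h)
  if (j < 3) abort(sprintf("mode estimator needs at least 3 instruments, got %d", j),
                   "mrmediate_insufficient_snps")
  wr <- wald_ratio(h$data$beta_exp, h$data$se_exp, h$data$beta_out, h$data$se_out)
  weights <- if (weighted) 1 / wr$se^2 else rep(1, j)
  est <- mode_core(wr$ratio, weights, phi)
  se <- parametric_bootstrap_se(h, function(bx, by, sy) {
    r <- by / bx
    wts <- if (weighted) (abs(bx) / sy)^2 else rep(1, length(r))
    mode_core(r, wts, phi)
  }, n_boot, seed)
  mr_result(if (weighted) "weighted_mode" else "simple_mode", est, se, j,
            outcome_binary = h$outcome_type == "binary")
}

#' Run the five MR estimators on one harmonized set
#'
#' IVW is always computed (the primary result); MR-Egger, weighted median and
#' the two mode estimators additionally require J >= 3 and are omitted below
#' that. The Egger intercept is carried in the `intercept_*` columns of the
#' Egger row.
#'
#' @param h a [harmonized_set].
#' @param ivw_variant `"mre"` or `"fixed"`.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param phi mode bandwidth factor.
#' @param seed RNG seed for the bootstraps.
#' @return A tidy data.frame, one row per method, with columns
#'   `exposure_id`, `outcome_id`, `method`, `n_snp`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `or_point`, `or_low`, `or_high`,
#'   `intercept_estimate`, `intercept_se`, `intercept_pval`.
#' @export
mr_all_methods <- function(h, ivw_variant = c("mre", "fixed"), n_boot = 1000,
                           phi = 1, seed = NULL) {
  ivw_variant <- match.arg(ivw_variant)
  j <- n_snps(h)
  variant <- if (j == 1) "fixed" else ivw_variant
  results <- list(mr_ivw(h, variant))
  intercept <- NULL
  if (j >= 3) {
    egger <- mr_egger(h)
    intercept <- egger$intercept
    results <- c(results, list(
      egger$slope,
      mr_weighted_median(h, n_boot = n_boot, seed = seed),
      mr_mode(h, weighted = FALSE, phi = phi, n_boot = n_boot, seed = seed),
      mr_mode(h, weighted = TRUE, phi = phi, n_boot = n_boot, seed = seed)
    ))
  }
  rows <- lapply(results, function(r) {
    data.frame(
      exposure_id = h$exposure_id, outcome_id = h$outcome_id,
      method = r$method, n_snp = r$n_snp, estimate = r$estimate, se = r$se,
      ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval,
      or_point = r$or_point, or_low = r$or_low, or_high = r$or_high,
      intercept_estimate = if (r$method == "egger") intercept$estimate else NA_real_,
      intercept_se = if (r$method == "egger") intercept$se else NA_real_,
      intercept_pval = if (r$method == "egger") intercept$pval else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
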