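# End-to-end orchestration: single-pair MR, the multi-exposure total-effect
# screen, reverse-direction MR, and the mediation run. All thresholds live in
# one validated config so a bare config reproduces the standard settings
# (P <= 5e-5, clump r2 < 0.01 within 10,000 kb, F > 10, alpha 0.05,
# proxy r2 >= 0.8).

#' Build a validated run configuration
#'
#' @param exposures list of [sumstats] objects, or character paths/globs to
#'   canonical-dialect TSVs.
#' @param mediators like `exposures`; needed only for [run_mediation()].
#' @param outcome a [sumstats] or a path.
#' @param ld optional [ld_matrix] or path; when absent, clumping is skipped
#'   and every instrument is flagged `no_ld_info`.
#' @param proxies optional [proxy_table] or path.
#' @param p_max instrument p-value threshold (inclusive), default 5e-5.
#' @param clump_r2 LD clumping threshold, default 0.01.
#' @param clump_kb clumping window in kb, default 10000.
#' @param f_min weak-instrument threshold (exclusive), default 10.
#' @param alpha significance level for screening gates, default 0.05.
#' @param proxy_r2_min minimum proxy LD, default 0.8.
#' @param ivw_variant `"mre"` or `"fixed"`.
#' @param n_boot bootstrap replicates for median/mode SEs, default 1000.
#' @param phi mode bandwidth factor, default 1.
#' @param screen_on `"nominal"` or `"fdr"` significance gate.
#' @param bidirectional also run reverse-direction MR per exposure.
#' @param seed RNG seed for all bootstraps, default 1.
#' @param out_dir optional output directory; when set, the run functions
#'   write their TSVs there.
#' @param exposure_type,mediator_type,outcome_type trait types used when
#'   reading from paths.
#' @return An object of class `mr_run_config`.
#' @export
run_config <- function(exposures = NULL, mediators = NULL, outcome = NULL,
                       ld = NULL, proxies = NULL,
                       p_max = 5e-5, clump_r2 = 0.01, clump_kb = 10000,
                       f_min = 10, alpha = 0.05, proxy_r2_min = 0.8,
                       ivw_variant = c("mre", "fixed"), n_boot = 1000, phi = 1,
                       screen_on = c("nominal", "fdr"), bidirectional = FALSE,
                       seed = 1L, out_dir = NULL,
                       exposure_type = "continuous", mediator_type = "continuous",
                       outcome_type = "binary") {
  ivw_variant <- match.arg(ivw_variant)
  screen_on <- match.arg(screen_on)
  check_range <- function(x, nm, lo, hi) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
      abort(sprintf("%s must be a scalar in [%g, %g]", nm, lo, hi), "mrmediate_bad_input")
    }
  }
  check_range(p_max, "p_max", .Machine$double.xmin, 1)
  check_range(clump_r2, "clump_r2", 0, 1)
  check_range(clump_kb, "clump_kb", 0, Inf)
  check_range(f_min, "f_min", 0, Inf)
  check_range(alpha, "alpha", .Machine$double.xmin, 1)
  check_range(proxy_r2_min, "proxy_r2_min", 0, 1)
  if (is.null(seed)) abort("seed is mandatory (bootstrap SEs must be reproducible)",
                           "mrmediate_bad_input")
  structure(
    list(exposures = exposures, mediators = mediators, outcome = outcome,
         ld = ld, proxies = proxies, p_max = p_max, clump_r2 = clump_r2,
         clump_kb = clump_kb, f_min = f_min, alpha = alpha,
         proxy_r2_min = proxy_r2_min, ivw_variant = ivw_variant,
         n_boot = n_boot, phi = phi, screen_on = screen_on,
         bidirectional = isTRUE(bidirectional), seed = as.integer(seed),
         out_dir = out_dir, exposure_type = exposure_type,
         mediator_type = mediator_type, outcome_type = outcome_type),
    class = "mr_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `exposures` / `mediators`
#' may be globs.
#'
#' @param path YAML file.
#' @return An `mr_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "mrmediate_io_error")
  cfg <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          "mrmediate_bad_input")
  }
  do.call(run_config, cfg)
}

# Resolve a config entry into a list of sumstats objects.
#' @keywords internal
resolve_sumstats <- function(x, trait_type) {
  if (is.null(x)) return(list())
  if (inherits(x, "sumstats")) return(stats::setNames(list(x), x$trait_id))
  if (is.list(x)) {
    out <- lapply(x, function(el) {
      if (inherits(el, "sumstats")) el
      else read_sumstats(el, trait_id = sub("\\.[^.]*$", "", basename(el)),
                         trait_type = trait_type)
    })
    names(out) <- vapply(out, function(s) s$trait_id, character(1))
    return(out)
  }
  if (is.character(x)) {
    files <- unlist(lapply(x, function(p) if (file.exists(p)) p else Sys.glob(p)))
    if (length(files) == 0) abort(sprintf("no files match '%s'", paste(x, collapse = ", ")),
                                  "mrmediate_io_error")
    return(resolve_sumstats(as.list(files), trait_type))
  }
  abort("cannot resolve sumstats input", "mrmediate_bad_input")
}

#' @keywords internal
resolve_ld <- function(x) {
  if (is.null(x) || inherits(x, "ld_matrix")) return(x)
  read_ld_matrix(x)
}

#' @keywords internal
resolve_proxies <- function(x) {
  if (is.null(x) || inherits(x, "proxy_table")) return(x)
  read_proxy_table(x)
}

#' Run the full single-pair MR workflow
#'
#' select instruments by p-value -> LD clump -> harmonize against the outcome
#' -> drop weak instruments -> five estimators -> sensitivity diagnostics.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param ld optional [ld_matrix]; without it clumping is skipped with a
#'   warning flag on every instrument.
#' @param proxies optional [proxy_table].
#' @param config an `mr_run_config` supplying thresholds (a default one is
#'   built if omitted).
#' @return list with `harmonized` (the final [harmonized_set]), `results`
#'   (tidy data.frame from [mr_all_methods()]) and `sensitivity`
#'   (a [sensitivity_report()], or NULL when J < 3).
#' @export
mr_single_pair <- function(exposure, outcome, ld = NULL, proxies = NULL,
                           config = run_config()) {
  sel <- select_by_pvalue(exposure, config$p_max)
  if (nrow(sel$records) == 0) {
    abort_no_instruments(exposure$trait_id, outcome$trait_id,
                         sprintf("no SNP at p <= %g", config$p_max))
  }
  if (!is.null(ld)) sel <- clump(sel, ld, config$clump_r2, config$clump_kb)
  h <- harmonize(sel, outcome, proxies = proxies, proxy_r2_min = config$proxy_r2_min)
  h <- filter_weak(h, config$f_min)
  results <- mr_all_methods(h, ivw_variant = config$ivw_variant,
                            n_boot = config$n_boot, phi = config$phi,
                            seed = config$seed)
  sens <- if (n_snps(h) >= 3) sensitivity_report(h, config$alpha, config$ivw_variant) else NULL
  list(harmonized = h, results = results, sensitivity = sens)
}

#' Reverse-direction (outcome-as-exposure) MR
#'
#' Runs the same pipeline with the roles swapped, using the outcome's own
#' instruments at the same thresholds. A reverse IVW p-value >= alpha
#' supports the assumed causal direction; with no reverse instruments the
#' check is recorded as `"untestable"` rather than a failure.
#'
#' @param exposure,outcome [sumstats] in their ORIGINAL roles.
#' @param ld,proxies,config as in [mr_single_pair()].
#' @return list with `reverse_ok` (`"yes"`, `"no"`, `"untestable"`),
#'   `reverse_pval`, and `results` (tidy data.frame or NULL).
#' @export
reverse_mr <- function(exposure, outcome, ld = NULL, proxies = NULL,
                       config = run_config()) {
  rev <- tryCatch(
    mr_single_pair(outcome, exposure, ld = ld, proxies = proxies, config = config),
    mrmediate_no_instruments = function(e) NULL
  )
  if (is.null(rev)) {
    return(list(reverse_ok = "untestable", reverse_pval = NA_real_, results = NULL))
  }
  p <- rev$results$pval[rev$results$method == "ivw"]
  list(reverse_ok = if (p >= config$alpha) "yes" else "no",
       reverse_pval = p, results = rev$results)
}

#' @keywords internal
write_tidy_tsv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
sensitivity_rows <- function(sens) {
  if (is.null(sens)) return(NULL)
  data.frame(
    exposure_id = sens$exposure_id, outcome_id = sens$outcome_id,
    n_snp = sens$n_snp,
    q_ivw = sens$q_ivw$Q, q_ivw_df = sens$q_ivw$df, q_ivw_pval = sens$q_ivw$pval,
    q_egger = sens$q_egger$Q, q_egger_df = sens$q_egger$df,
    q_egger_pval = sens$q_egger$pval,
    egger_intercept = sens$egger_intercept$estimate,
    egger_intercept_se = sens$egger_intercept$se,
    egger_intercept_pval = sens$egger_intercept$pval,
    loo_min = min(sens$loo$estimate), loo_max = max(sens$loo$estimate),
    stringsAsFactors = FALSE
  )
}

#' Run the total-effect screen over many exposures
#'
#' For every exposure: select -> clump -> harmonize -> filter weak -> five
#' estimators -> sensitivity -> screening gates. A failing exposure (e.g. no
#' instruments) is recorded as excluded with its reason and never aborts the
#' batch. When `config$bidirectional` is TRUE a reverse-direction MR is run
#' per exposure and recorded descriptively. With `config$out_dir` set, writes
#' `screen_records.tsv`, `mr_results.tsv` and `sensitivity.tsv`
#' (deterministically formatted, so identical configs give identical bytes).
#'
#' @param config an `mr_run_config` with `exposures` and `outcome`.
#' @return list with `screen` (ScreenRecord data.frame), `results` (all
#'   per-method rows), `sensitivity` (per-exposure diagnostic rows), and
#'   `pairs` (the per-exposure raw objects, for downstream reuse).
#' @export
run_total_screen <- function(config) {
  stopifnot(inherits(config, "mr_run_config"))
  exposures <- resolve_sumstats(config$exposures, config$exposure_type)
  if (length(exposures) == 0) abort("config has no exposures", "mrmediate_bad_input")
  outcome <- resolve_sumstats(config$outcome, config$outcome_type)[[1]]
  ld <- resolve_ld(config$ld)
  proxies <- resolve_proxies(config$proxies)

  pair_results <- list()
  failures <- list()
  for (id in names(exposures)) {
    pr <- tryCatch(
      suppressWarnings(mr_single_pair(exposures[[id]], outcome, ld = ld,
                                      proxies = proxies, config = config)),
      mrmediate_error = function(e) e
    )
    if (inherits(pr, "error")) {
      message(sprintf("[screen] exposure %s skipped: %s", id, conditionMessage(pr)))
      failures[[id]] <- conditionMessage(pr)
      next
    }
    if (config$bidirectional) {
      rev <- suppressWarnings(reverse_mr(exposures[[id]], outcome, ld = ld,
                                         proxies = proxies, config = config))
      pr$reverse_pval <- rev$reverse_pval
    }
    message(sprintf("[screen] exposure %s: J = %d instruments", id, n_snps(pr$harmonized)))
    pair_results[[id]] <- pr
  }

  screenable <- Filter(function(pr) !is.null(pr$sensitivity), pair_results)
  screen <- if (length(screenable) > 0) {
    screen_total_effects(screenable, alpha = config$alpha, screen_on = config$screen_on)
  } else {
    NULL
  }
  # exposures that ran but lack the full five-method/sensitivity panel
  thin <- setdiff(names(pair_results), names(screenable))
  extra <- c(
    lapply(thin, function(id) excluded_row(id, "insufficient instruments for full method panel")),
    lapply(names(failures), function(id) excluded_row(id, failures[[id]]))
  )
  screen <- do.call(rbind, c(list(screen), extra))
  screen <- screen[order(match(screen$exposure_id, names(exposures))), , drop = FALSE]
  rownames(screen) <- NULL

  results <- do.call(rbind, lapply(pair_results, `[[`, "results"))
  rownames(results) <- NULL
  sens <- do.call(rbind, lapply(pair_results, function(pr) sensitivity_rows(pr$sensitivity)))
  if (!is.null(sens)) rownames(sens) <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tidy_tsv(screen, file.path(config$out_dir, "screen_records.tsv"))
    write_tidy_tsv(results, file.path(config$out_dir, "mr_results.tsv"))
    if (!is.null(sens)) write_tidy_tsv(sens, file.path(config$out_dir, "sensitivity.tsv"))
  }
  list(screen = screen, results = results, sensitivity = sens, pairs = pair_results)
}

#' @keywords internal
excluded_row <- function(id, reason) {
  data.frame(
    exposure_id = id, ivw_estimate = NA_real_, ivw_pval = NA_real_,
    fdr_pval = NA_real_, direction_consistent = NA, pleiotropy_ok = NA,
    heterogeneity_ok = NA, reverse_ok = NA_character_,
    verdict = "excluded", reason = reason, stringsAsFactors = FALSE
  )
}

#' Run the two-step mediation workflow
#'
#' Computes the three MR legs — exposure to outcome (the total-effect screen),
#' mediator to outcome, and exposure to mediator for every candidate pair —
#' then assembles pairs and decomposes their effects with
#' [two_step_mediation()]. Per-triplet failures are logged and skipped. With
#' `config$out_dir` set, writes `mediation_pairs.tsv` (header always written,
#' zero rows allowed).
#'
#' @param config an `mr_run_config` with `exposures`, `mediators`, `outcome`.
#' @param require_mediator,require_path entry gates passed to
#'   [assemble_pairs()].
#' @return list with `screen`, `mediation` (the pair decomposition
#'   data.frame), `med_out` and `exp_med` (the leg IVW tables).
#' @export
run_mediation <- function(config, require_mediator = TRUE, require_path = TRUE) {
  stopifnot(inherits(config, "mr_run_config"))
  mediators <- resolve_sumstats(config$mediators, config$mediator_type)
  outcome <- resolve_sumstats(config$outcome, config$outcome_type)[[1]]
  ld <- resolve_ld(config$ld)
  proxies <- resolve_proxies(config$proxies)

  total_run <- run_total_screen(config)
  screen <- total_run$screen
  ivw_rows <- total_run$results[total_run$results$method == "ivw", , drop = FALSE]
  total_results <- data.frame(
    exposure_id = ivw_rows$exposure_id, estimate = ivw_rows$estimate,
    se = ivw_rows$se, pval = ivw_rows$pval, stringsAsFactors = FALSE
  )

  leg_ivw <- function(exposure, out_ss) {
    pr <- suppressWarnings(mr_single_pair(exposure, out_ss, ld = ld,
                                          proxies = proxies, config = config))
    row <- pr$results[pr$results$method == "ivw", ]
    list(estimate = row$estimate, se = row$se, pval = row$pval)
  }

  med_out <- list()
  for (m_id in names(mediators)) {
    fit <- tryCatch(leg_ivw(mediators[[m_id]], outcome), mrmediate_error = function(e) e)
    if (inherits(fit, "error")) {
      message(sprintf("[mediation] mediator %s -> outcome skipped: %s",
                      m_id, conditionMessage(fit)))
      next
    }
    med_out[[m_id]] <- data.frame(mediator_id = m_id, estimate = fit$estimate,
                                  se = fit$se, pval = fit$pval, stringsAsFactors = FALSE)
  }
  med_out <- if (length(med_out) > 0) do.call(rbind, med_out) else
    data.frame(mediator_id = character(), estimate = numeric(), se = numeric(),
               pval = numeric(), stringsAsFactors = FALSE)
  rownames(med_out) <- NULL

  exposures <- resolve_sumstats(config$exposures, config$exposure_type)
  screened_x <- screen$exposure_id[screen$verdict != "excluded"]
  cand_m <- if (require_mediator) med_out$mediator_id[med_out$pval < config$alpha] else
    med_out$mediator_id
  exp_med <- list()
  for (x_id in intersect(names(exposures), screened_x)) {
    for (m_id in cand_m) {
      fit <- tryCatch(leg_ivw(exposures[[x_id]], mediators[[m_id]]),
                      mrmediate_error = function(e) e)
      if (inherits(fit, "error")) {
        message(sprintf("[mediation] %s -> %s skipped: %s", x_id, m_id,
                        conditionMessage(fit)))
        next
      }
      exp_med[[paste(x_id, m_id, sep = "|")]] <- data.frame(
        exposure_id = x_id, mediator_id = m_id, estimate = fit$estimate,
        se = fit$se, pval = fit$pval, stringsAsFactors = FALSE
      )
    }
  }
  exp_med <- if (length(exp_med) > 0) do.call(rbind, exp_med) else
    data.frame(exposure_id = character(), mediator_id = character(),
               estimate = numeric(), se = numeric(), pval = numeric(),
               stringsAsFactors = FALSE)
  rownames(exp_med) <- NULL

  mediation <- assemble_pairs(
    screen, total_results, exp_med, med_out, alpha = config$alpha,
    outcome_id = outcome$trait_id,
    require_mediator = require_mediator, require_path = require_path
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tidy_tsv(mediation, file.path(config$out_dir, "mediation_pairs.tsv"))
  }
  list(screen = screen, mediation = mediation, med_out = med_out, exp_med = exp_med)
}
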