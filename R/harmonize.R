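# Harmonization: join exposure and outcome summary statistics on shared SNPs,
# align effect alleles (flipping outcome betas when the allele pair is
# swapped), exclude palindromic SNPs, and optionally substitute LD proxies.

#' Construct an LD proxy lookup table
#'
#' @param df data.frame with columns `target_snp`, `proxy_snp`, `r2`,
#'   `proxy_effect_allele`, `target_effect_allele`, `proxy_other_allele`,
#'   `target_other_allele`. The allele correspondence maps the proxy's
#'   alleles onto the target's so a proxy association can stand in for the
#'   missing target SNP.
#' @return An object of class `proxy_table`.
#' @export
proxy_table <- function(df) {
  need <- c("target_snp", "proxy_snp", "r2", "proxy_effect_allele",
            "target_effect_allele", "proxy_other_allele", "target_other_allele")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("proxy table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
          "mrmediate_bad_input")
  }
  df <- df[need]
  df$r2 <- as.numeric(df$r2)
  for (col in grep("allele", need, value = TRUE)) df[[col]] <- toupper(as.character(df[[col]]))
  if (any(!is.finite(df$r2) | df$r2 < 0 | df$r2 > 1)) {
    abort("proxy r2 values must lie in [0, 1]", "mrmediate_bad_input")
  }
  bad_corr <- df$proxy_effect_allele == df$proxy_other_allele |
    df$target_effect_allele == df$target_other_allele
  if (any(bad_corr)) abort("proxy allele correspondence is not a bijection", "mrmediate_bad_input")
  structure(df, class = c("proxy_table", "data.frame"))
}

#' Read a proxy table from TSV
#'
#' @param path TSV with the columns documented in [proxy_table()].
#' @return A `proxy_table`.
#' @export
read_proxy_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "mrmediate_io_error")
  proxy_table(utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
}

#' Construct a harmonized exposure/outcome instrument set directly
#'
#' Low-level constructor used by [harmonize()] and convenient for building
#' estimator inputs in simulations and tests. Every row refers to a shared
#' effect allele for both traits.
#'
#' @param data data.frame with at least `snp_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`; optional `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf_exp`, `pval_exp`, `pval_out`, `provenance`.
#' @param exposure_id,outcome_id trait identifiers.
#' @param outcome_type `"continuous"` or `"binary"` — controls whether
#'   downstream estimates are exponentiated to odds ratios.
#' @return An object of class `harmonized_set`.
#' @export
harmonized_set <- function(data, exposure_id, outcome_id,
                           outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  need <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("harmonized data lacks column(s): %s", paste(missing_cols, collapse = ", ")),
          "mrmediate_bad_input")
  }
  if (any(data$se_exp <= 0) || any(data$se_out <= 0)) {
    abort("standard errors must be positive", "mrmediate_bad_input")
  }
  if (all(c("effect_allele", "other_allele") %in% names(data)) &&
      any(is_palindromic(data$effect_allele, data$other_allele))) {
    abort("palindromic SNP present in harmonized data", "mrmediate_bad_input")
  }
  if (!"provenance" %in% names(data)) data$provenance <- "direct"
  if (!"f_stat" %in% names(data)) data$f_stat <- (data$beta_exp / data$se_exp)^2
  rownames(data) <- NULL
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id,
         outcome_type = outcome_type, data = data),
    class = "harmonized_set"
  )
}

#' Number of instruments in a harmonized set
#' @param h a `harmonized_set`.
#' @return integer SNP count.
#' @export
n_snps <- function(h) nrow(h$data)

#' Harmonize exposure and outcome summary statistics
#'
#' Joins the two tables on `snp_id` and aligns each row to the exposure's
#' effect allele. Outcome rows whose effect/other alleles are swapped
#' relative to the exposure have their beta sign flipped (provenance
#' `"flipped"`). Palindromic SNPs (A/T, C/G) are excluded unconditionally —
#' no allele-frequency rescue is attempted. When a target SNP is absent from
#' the outcome and a proxy table is supplied, the best proxy with
#' `r2 >= proxy_r2_min` substitutes for it via its allele correspondence
#' (provenance `"proxy"`; direct matches always win over proxies). Rows with
#' irreconcilable allele pairs are dropped and counted.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param proxies optional [proxy_table].
#' @param proxy_r2_min minimum LD r-squared for proxy substitution
#'   (inclusive), default 0.8.
#' @return A [harmonized_set] with per-row provenance and drop counts in
#'   `attr(, "counts")`.
#' @export
harmonize <- function(exposure, outcome, proxies = NULL, proxy_r2_min = 0.8) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$records
  out <- outcome$records

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  n_palindromic <- sum(pal)
  ex <- ex[!pal, , drop = FALSE]

  out_idx <- match(ex$snp_id, out$snp_id)
  matched <- !is.na(out_idx)
  ea_o <- out$effect_allele[out_idx]
  oa_o <- out$other_allele[out_idx]
  direct <- matched & ea_o == ex$effect_allele & oa_o == ex$other_allele
  flipped <- matched & ea_o == ex$other_allele & oa_o == ex$effect_allele
  n_irreconcilable <- sum(matched & !direct & !flipped)
  n_unmatched <- 0L

  keep <- which(direct | flipped)
  data <- data.frame(
    snp_id = ex$snp_id[keep], chrom = ex$chrom[keep], pos = ex$pos[keep],
    effect_allele = ex$effect_allele[keep], other_allele = ex$other_allele[keep],
    eaf_exp = ex$eaf[keep],
    beta_exp = ex$beta[keep], se_exp = ex$se[keep], pval_exp = ex$pval[keep],
    beta_out = ifelse(flipped[keep], -1, 1) * out$beta[out_idx[keep]],
    se_out = out$se[out_idx[keep]], pval_out = out$pval[out_idx[keep]],
    provenance = ifelse(flipped[keep], "flipped", "direct"),
    stringsAsFactors = FALSE
  )

  # unmatched exposure SNPs: proxy substitution where possible
  proxy_rows <- list()
  for (i in which(!matched)) {
    ex_row <- ex[i, ]
    if (is.null(proxies)) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    cand <- proxies[proxies$target_snp == ex_row$snp_id &
                      proxies$r2 >= proxy_r2_min &
                      proxies$proxy_snp %in% out$snp_id, , drop = FALSE]
    if (nrow(cand) == 0) {
      n_unmatched <- n_unmatched + 1L
      next
    }
    cand <- cand[order(-cand$r2, cand$proxy_snp), , drop = FALSE]
    px <- cand[1, ]
    k <- match(px$proxy_snp, out$snp_id)
    # translate the proxy's observed alleles into target-allele space
    map <- c(stats::setNames(px$target_effect_allele, px$proxy_effect_allele),
             stats::setNames(px$target_other_allele, px$proxy_other_allele))
    ea_t <- unname(map[out$effect_allele[k]])
    oa_t <- unname(map[out$other_allele[k]])
    flip <- if (!is.na(ea_t) && !is.na(oa_t) &&
                ea_t == ex_row$effect_allele && oa_t == ex_row$other_allele) {
      FALSE
    } else if (!is.na(ea_t) && !is.na(oa_t) &&
               ea_t == ex_row$other_allele && oa_t == ex_row$effect_allele) {
      TRUE
    } else {
      n_irreconcilable <- n_irreconcilable + 1L
      NA
    }
    if (is.na(flip)) next
    proxy_rows[[length(proxy_rows) + 1L]] <- data.frame(
      snp_id = ex_row$snp_id, chrom = ex_row$chrom, pos = ex_row$pos,
      effect_allele = ex_row$effect_allele, other_allele = ex_row$other_allele,
      eaf_exp = ex_row$eaf,
      beta_exp = ex_row$beta, se_exp = ex_row$se, pval_exp = ex_row$pval,
      beta_out = if (flip) -out$beta[k] else out$beta[k],
      se_out = out$se[k], pval_out = out$pval[k],
      provenance = "proxy", stringsAsFactors = FALSE
    )
  }
  if (length(proxy_rows) > 0) {
    data <- rbind(data, do.call(rbind, proxy_rows))
    data <- data[order(match(data$snp_id, ex$snp_id)), , drop = FALSE]
  }
  if (nrow(data) == 0) {
    abort_no_instruments(exposure$trait_id, outcome$trait_id,
                         "empty intersection after harmonization")
  }
  h <- harmonized_set(data, exposure$trait_id, outcome$trait_id,
                      outcome_type = outcome$trait_type)
  attr(h, "counts") <- c(
    palindromic = n_palindromic,
    unmatched = n_unmatched,
    irreconcilable = n_irreconcilable,
    proxy = sum(data$provenance == "proxy")
  )
  h
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s (%s outcome), %d instruments\n",
              x$exposure_id, x$outcome_id, x$outcome_type, n_snps(x)))
  counts <- attr(x, "counts")
  if (!is.null(counts)) {
    cat("dropped:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  }
  invisible(x)
}
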