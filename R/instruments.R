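# Instrument selection: genome-wide significance threshold, greedy LD
# clumping within a physical window, per-SNP F statistics and
# weak-instrument removal.

#' Construct an LD matrix
#'
#' @param r2 square numeric matrix of squared correlations with unit diagonal;
#'   row/column names are SNP identifiers (or supply `snp_ids`).
#' @param snp_ids optional character vector of SNP ids (overrides dimnames).
#' @return An object of class `ld_matrix` (a named square matrix).
#' @export
ld_matrix <- function(r2, snp_ids = NULL) {
  r2 <- as.matrix(r2)
  if (!is.null(snp_ids)) dimnames(r2) <- list(snp_ids, snp_ids)
  if (is.null(rownames(r2))) abort("LD matrix needs SNP identifiers", "mrmediate_bad_input")
  if (nrow(r2) != ncol(r2) || !identical(rownames(r2), colnames(r2))) {
    abort("LD matrix must be square with matching row/column SNP ids", "mrmediate_bad_input")
  }
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    abort("LD r2 values must lie in [0, 1]", "mrmediate_bad_input")
  }
  if (max(abs(r2 - t(r2))) > 1e-8) abort("LD matrix must be symmetric", "mrmediate_bad_input")
  if (any(abs(diag(r2) - 1) > 1e-8)) abort("LD matrix diagonal must be 1", "mrmediate_bad_input")
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Read an LD matrix from TSV
#'
#' Expects a square matrix with a header row of SNP ids and the same ids in
#' the first column.
#'
#' @param path TSV path.
#' @return An [ld_matrix].
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "mrmediate_io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = 1, stringsAsFactors = FALSE)
  ld_matrix(as.matrix(df))
}

#' Write an LD matrix to TSV
#' @param ld an [ld_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  m <- unclass(ld)
  out <- data.frame(snp_id = rownames(m),
                    apply(m, 2, fmt_num),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter summary statistics by association p-value
#'
#' Retains SNPs with `pval <= p_max` (boundary inclusive), preserving input
#' order. The default reproduces the instrument-screening threshold
#' P <= 5e-5 commonly used for molecular-phenotype exposures.
#'
#' @param s a [sumstats] object.
#' @param p_max inclusive significance threshold.
#' @return A [sumstats] with the retained subset (possibly zero rows kept as
#'   an empty records table; downstream operations raise on emptiness).
#' @export
select_by_pvalue <- function(s, p_max = 5e-5) {
  stopifnot(inherits(s, "sumstats"))
  if (!is.numeric(p_max) || length(p_max) != 1 || p_max <= 0 || p_max > 1) {
    abort("p_max must be a scalar in (0, 1]", "mrmediate_bad_input")
  }
  out <- s
  out$records <- s$records[s$records$pval <= p_max, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Standard greedy clumping: candidates are ranked by ascending p-value
#' (ties broken by `snp_id` so the result is invariant to input row order);
#' the best remaining SNP is retained and every other SNP on the same
#' chromosome within `window_kb` kilobases with `r2 >= r2_max` against it is
#' removed. SNPs absent from the LD matrix are retained with an audit flag
#' `no_ld_info` and a warning. The per-candidate disposition is attached as
#' `attr(, "audit")` (`retained`, `clumped_to:<snp>`, or `no_ld_info`).
#'
#' @param s a [sumstats] object.
#' @param ld an [ld_matrix] covering (a superset of) the SNPs in `s`.
#' @param r2_max LD threshold: retained SNPs are pairwise `r2 < r2_max`
#'   within the window. Default 0.01.
#' @param window_kb physical window in kilobases. Default 10000 (10 Mb).
#' @return A [sumstats] of retained SNPs (input order preserved).
#' @export
clump <- function(s, ld, r2_max = 0.01, window_kb = 10000) {
  stopifnot(inherits(s, "sumstats"))
  if (!inherits(ld, "ld_matrix")) ld <- ld_matrix(ld)
  rec <- s$records
  if (nrow(rec) == 0) {
    attr(s, "audit") <- data.frame(snp_id = character(), disposition = character(),
                                   stringsAsFactors = FALSE)
    return(s)
  }
  in_ld <- rec$snp_id %in% rownames(ld)
  if (any(!in_ld)) {
    warn_structured(
      sprintf("%d SNP(s) missing from the LD matrix were retained with flag no_ld_info",
              sum(!in_ld)),
      "mrmediate_no_ld_info", data = list(snps = rec$snp_id[!in_ld])
    )
  }

  ord <- order(rec$pval, rec$snp_id)
  queue <- rec$snp_id[ord]
  disposition <- stats::setNames(rep(NA_character_, nrow(rec)), rec$snp_id)
  disposition[rec$snp_id[!in_ld]] <- "no_ld_info"

  pos <- stats::setNames(rec$pos, rec$snp_id)
  chrom <- stats::setNames(rec$chrom, rec$snp_id)
  window_bp <- window_kb * 1000

  while (length(queue) > 0) {
    top <- queue[1]
    queue <- queue[-1]
    if (!is.na(disposition[top])) next  # already dispositioned (no_ld_info)
    disposition[top] <- "retained"
    if (!(top %in% rownames(ld)) || length(queue) == 0) next
    others <- queue[is.na(disposition[queue])]
    others <- others[others %in% rownames(ld)]
    if (length(others) == 0) next
    same_chr <- chrom[others] == chrom[top]
    in_window <- abs(pos[others] - pos[top]) <= window_bp
    high_ld <- ld[top, others] >= r2_max
    clumped <- others[same_chr & in_window & high_ld]
    disposition[clumped] <- paste0("clumped_to:", top)
    queue <- setdiff(queue, clumped)
  }

  keep <- disposition[rec$snp_id] %in% c("retained", "no_ld_info")
  out <- s
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "audit") <- data.frame(
    snp_id = rec$snp_id,
    disposition = unname(disposition[rec$snp_id]),
    stringsAsFactors = FALSE
  )
  out
}

#' Clump audit trail
#' @param s the output of [clump()].
#' @return data.frame of per-candidate dispositions.
#' @export
clump_audit <- function(s) attr(s, "audit")

#' Per-SNP instrument-strength F statistic
#'
#' Computed as the square of the marginal Wald z, `(beta/se)^2`, the standard
#' summary-data surrogate requiring no sample-size or allele-frequency
#' fields. F < 10 conventionally flags a weak instrument.
#'
#' @param beta_exp,se_exp exposure effect and standard error (vectorized).
#' @return Nonnegative F statistic(s).
#' @export
f_statistic <- function(beta_exp, se_exp) {
  if (any(!is.finite(se_exp)) || any(se_exp <= 0)) {
    abort("se_exp must be positive", "mrmediate_bad_input")
  }
  (beta_exp / se_exp)^2
}

#' Remove weak instruments from a harmonized set
#'
#' Retains rows with F strictly greater than `f_min` (instruments with
#' F <= 10 are considered weak under the default).
#'
#' @param h a [harmonized_set].
#' @param f_min weak-instrument threshold (exclusive). Default 10.
#' @return The filtered [harmonized_set]; removed SNP ids are recorded in
#'   `attr(, "weak_removed")`.
#' @export
filter_weak <- function(h, f_min = 10) {
  stopifnot(inherits(h, "harmonized_set"))
  if (n_snps(h) == 0) abort_no_instruments(h$exposure_id, h$outcome_id, "empty input")
  f <- f_statistic(h$data$beta_exp, h$data$se_exp)
  keep <- f > f_min
  if (!any(keep)) {
    abort_no_instruments(h$exposure_id, h$outcome_id,
                         sprintf("all %d instruments weak (F <= %g)", n_snps(h), f_min))
  }
  removed <- h$data$snp_id[!keep]
  h$data <- h$data[keep, , drop = FALSE]
  h$data$f_stat <- f[keep]
  rownames(h$data) <- NULL
  attr(h, "weak_removed") <- removed
  h
}
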