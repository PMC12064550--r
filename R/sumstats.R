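# GWAS summary-statistics container and delimited-text I/O.
#
# Canonical on-disk dialect: tab-separated, header
#   snp_id chrom pos effect_allele other_allele eaf beta se pval n
# with "NA" for missing optionals (eaf, n). Positions are 1-based.

SUMSTATS_COLUMNS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)
SUMSTATS_MANDATORY <- setdiff(SUMSTATS_COLUMNS, c("eaf", "n"))

#' Construct a GWAS summary-statistics object
#'
#' Bundles one trait's per-SNP association table with its identity and scale.
#' Rows violating the per-record invariants (single-nucleotide alleles,
#' `effect_allele != other_allele`, `se > 0`, `pval` in (0, 1], finite `beta`,
#' `eaf` in (0, 1) when present) are dropped with a structured warning.
#' Duplicate `snp_id`s keep the row with the smallest p-value.
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and optionally
#'   `eaf`, `n`.
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"continuous"` (beta in SD units) or `"binary"`
#'   (beta is a log odds ratio, so OR = exp(beta)).
#' @return An object of class `sumstats`: a list with elements `trait_id`,
#'   `trait_type` and `records` (the validated data.frame).
#' @export
sumstats <- function(records, trait_id, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  if (!is.data.frame(records)) abort("`records` must be a data.frame", "mrmediate_bad_input")
  missing_cols <- setdiff(SUMSTATS_MANDATORY, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", ")),
          "mrmediate_bad_input")
  }
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  if (!"n" %in% names(records)) records$n <- NA_real_
  records <- records[SUMSTATS_COLUMNS]

  val <- validate_gwas_records(records)
  records <- val$records
  if (val$n_dropped > 0) {
    warn_structured(
      sprintf("dropped %d invalid record(s) for trait '%s' (%s)",
              val$n_dropped, trait_id,
              paste(sprintf("%s: %d", names(val$reasons), val$reasons), collapse = ", ")),
      "mrmediate_dropped_records",
      data = list(n_dropped = val$n_dropped, reasons = val$reasons)
    )
  }

  # duplicate snp_id: keep the strongest (smallest p-value) signal
  if (anyDuplicated(records$snp_id)) {
    ord <- order(records$pval, records$snp_id)
    records <- records[ord, , drop = FALSE]
    dup <- duplicated(records$snp_id)
    n_dup <- sum(dup)
    records <- records[!dup, , drop = FALSE]
    records <- records[order(as.integer(rownames(records))), , drop = FALSE]
    warn_structured(
      sprintf("removed %d duplicate snp_id row(s) for trait '%s', keeping smallest p-value",
              n_dup, trait_id),
      "mrmediate_duplicate_snps", data = list(n_dup = n_dup)
    )
  }
  if (nrow(records) == 0) {
    abort(sprintf("no valid records for trait '%s'", trait_id), "mrmediate_empty_sumstats")
  }
  rownames(records) <- NULL
  structure(
    list(trait_id = trait_id, trait_type = trait_type, records = records),
    class = "sumstats"
  )
}

# Row-level invariant enforcement; returns kept rows and drop accounting.
#' @keywords internal
validate_gwas_records <- function(records) {
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  ok_allele <- records$effect_allele %in% NUCLEOTIDES &
    records$other_allele %in% NUCLEOTIDES
  ok_distinct <- ok_allele & records$effect_allele != records$other_allele
  ok_se <- is.finite(records$se) & records$se > 0
  ok_beta <- is.finite(records$beta)
  ok_pval <- is.finite(records$pval) & records$pval > 0 & records$pval <= 1
  ok_pos <- !is.na(records$snp_id) & nzchar(records$snp_id) &
    !is.na(records$chrom) & is.finite(records$pos) & records$pos >= 1
  ok_eaf <- is.na(records$eaf) | (records$eaf > 0 & records$eaf < 1)
  ok_n <- is.na(records$n) | (is.finite(records$n) & records$n > 0)

  keep <- ok_distinct & ok_se & ok_beta & ok_pval & ok_pos & ok_eaf & ok_n
  keep[is.na(keep)] <- FALSE
  reasons <- c(
    allele = sum(!ok_distinct, na.rm = TRUE),
    se = sum(ok_distinct & !ok_se, na.rm = TRUE),
    beta = sum(ok_distinct & ok_se & !ok_beta, na.rm = TRUE),
    pval = sum(ok_distinct & ok_se & ok_beta & !ok_pval, na.rm = TRUE),
    position = sum(ok_distinct & ok_se & ok_beta & ok_pval & !ok_pos, na.rm = TRUE),
    eaf = sum(ok_distinct & ok_se & ok_beta & ok_pval & ok_pos & !ok_eaf, na.rm = TRUE),
    n = sum(ok_distinct & ok_se & ok_beta & ok_pval & ok_pos & ok_eaf & !ok_n, na.rm = TRUE)
  )
  list(
    records = records[keep, , drop = FALSE],
    n_dropped = sum(!keep),
    reasons = reasons[reasons > 0]
  )
}

#' Read GWAS summary statistics from delimited text
#'
#' @param path path to a delimited text file with a header row.
#' @param trait_id trait identifier to attach.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param column_map optional named character vector mapping dialect column
#'   names (names) to canonical names (values), e.g.
#'   `c(rsid = "snp_id", effect = "beta")`, used to ingest FinnGen / IEU-style
#'   headers.
#' @param sep field separator, tab by default.
#' @return A [sumstats] object. Rows violating record invariants are dropped
#'   and counted in a structured warning.
#' @export
read_sumstats <- function(path, trait_id, trait_type = c("continuous", "binary"),
                          column_map = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "mrmediate_io_error")
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE, comment.char = "")
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(df))
    hit <- !is.na(idx)
    names(df)[idx[hit]] <- unname(column_map[hit])
  }
  missing_cols <- setdiff(SUMSTATS_MANDATORY, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("input '%s' lacks mandatory column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          "mrmediate_bad_input")
  }
  sumstats(df, trait_id = trait_id, trait_type = trait_type)
}

#' Write GWAS summary statistics in the canonical TSV dialect
#'
#' Numeric fields are written with 10 significant digits so that
#' `read_sumstats(write_sumstats(s))` reproduces `s` field-for-field.
#' Missing optionals (`eaf`, `n`) are written as `"NA"`.
#'
#' @param s a [sumstats] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  stopifnot(inherits(s, "sumstats"))
  if (nrow(s$records) == 0) abort("refusing to write empty sumstats", "mrmediate_empty_sumstats")
  rec <- s$records
  out <- data.frame(
    snp_id = rec$snp_id,
    chrom = rec$chrom,
    pos = format(as.integer(rec$pos), scientific = FALSE, trim = TRUE),
    effect_allele = rec$effect_allele,
    other_allele = rec$other_allele,
    eaf = fmt_num(rec$eaf),
    beta = fmt_num(rec$beta),
    se = fmt_num(rec$se),
    pval = fmt_num(rec$pval),
    n = fmt_num(rec$n),
    stringsAsFactors = FALSE
  )
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    abort(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
          "mrmediate_io_error")
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d SNPs\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  print(utils::head(x$records, 5))
  if (nrow(x$records) > 5) cat(sprintf("... %d more rows\n", nrow(x$records) - 5))
  invisible(x)
}
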