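# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mrmediate_error")))
}

#' @keywords internal
abort_no_instruments <- function(exposure_id, outcome_id = NULL, reason = "") {
  msg <- sprintf(
    "no instruments remain for exposure '%s'%s%s",
    exposure_id,
    if (is.null(outcome_id)) "" else sprintf(" against outcome '%s'", outcome_id),
    if (nzchar(reason)) paste0(" (", reason, ")") else ""
  )
  abort(msg, "mrmediate_no_instruments")
}

#' @keywords internal
warn_structured <- function(msg, class, data = list()) {
  w <- warningCondition(msg, class = c(class, "mrmediate_warning"))
  for (nm in names(data)) attr(w, nm) <- data[[nm]]
  warning(w)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded subroutines do not perturb outer simulations.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

NUCLEOTIDES <- c("A", "C", "G", "T")

# A/T and C/G pairs cannot be resolved from allele labels alone.
#' @keywords internal
is_palindromic <- function(effect_allele, other_allele) {
  pair <- paste0(effect_allele, other_allele)
  pair %in% c("AT", "TA", "CG", "GC")
}

# Deterministic decimal formatting used by every on-disk writer.
#' @keywords internal
fmt_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' @keywords internal
two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}
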