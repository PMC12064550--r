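# Shared fixture builders: all test data is generated in code.

# Minimal well-formed sumstats records table; override any column.
make_records <- function(.n = 3, ...) {
  base <- data.frame(
    snp_id = sprintf("rs%d", seq_len(.n)),
    chrom = rep("1", .n),
    pos = seq_len(.n) * 1e6,
    effect_allele = rep("A", .n),
    other_allele = rep("G", .n),
    eaf = rep(0.3, .n),
    beta = seq(0.1, by = 0.05, length.out = .n),
    se = rep(0.01, .n),
    pval = rep(1e-8, .n),
    n = rep(10000, .n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

make_ss <- function(.n = 3, trait_id = "trait", trait_type = "continuous", ...) {
  sumstats(make_records(.n, ...), trait_id = trait_id, trait_type = trait_type)
}

# Harmonized set straight from effect vectors (alleles synthetic non-palindromic).
make_hset <- function(bx, by, sx = rep(0.01, length(bx)), sy = rep(0.01, length(bx)),
                      outcome_type = "continuous") {
  harmonized_set(
    data.frame(
      snp_id = sprintf("rs%d", seq_along(bx)),
      beta_exp = bx, se_exp = sx, beta_out = by, se_out = sy,
      stringsAsFactors = FALSE
    ),
    exposure_id = "X", outcome_id = "Y", outcome_type = outcome_type
  )
}

# Hand-built five-method result bundle for exercising the screening gates.
fake_pair <- function(ests, ivw_p = 0.01, int_p = 0.4, q_p = 0.3, reverse_pval = NULL) {
  methods <- c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode")
  res <- data.frame(method = methods, estimate = ests, pval = 0.02,
                    stringsAsFactors = FALSE)
  res$pval[res$method == "ivw"] <- ivw_p
  list(
    results = res,
    sensitivity = list(egger_intercept = list(pval = int_p), q_ivw = list(pval = q_p)),
    reverse_pval = reverse_pval
  )
}

# Independent weighted-median oracle: direct interpolation over the sorted
# cumulative-mass curve, written without reference to the implementation.
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(r[1])
  if (0.5 >= cum[length(cum)]) return(r[length(r)])
  below <- max(which(cum < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

# Independent greedy-clump oracle: literal re-implementation of the stated
# procedure (sort by p-value with lexicographic snp_id tie-break, retain the
# best, drop everything in window with r2 >= threshold, repeat).
oracle_clump <- function(snp_id, chrom, pos, pval, r2, r2_max, window_kb) {
  ord <- order(pval, snp_id)
  ids <- snp_id[ord]
  names(chrom) <- names(pos) <- snp_id
  retained <- character(0)
  while (length(ids) > 0) {
    top <- ids[1]
    retained <- c(retained, top)
    drop <- vapply(ids[-1], function(s) {
      chrom[s] == chrom[top] &&
        abs(pos[s] - pos[top]) <= window_kb * 1000 &&
        r2[top, s] >= r2_max
    }, logical(1))
    ids <- ids[-1][!drop]
  }
  retained
}
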