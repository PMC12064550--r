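# Synthetic GWAS summary-statistics generator with a known three-node causal
# structure: exposure X -> mediator M -> outcome Y plus a direct X -> Y
# effect. Summary statistics are generated directly (no individual-level
# genotypes): each observed beta is the true marginal effect plus normal
# sampling noise with the analytic standard error
# se = 1/sqrt(2 * n * maf * (1 - maf)) for a standardized trait, which makes
# the noise model itself checkable.
#
# Three disjoint sets of J index SNPs are generated: exposure-specific
# instruments (effect gamma_j on X, b1*gamma_j on M, theta_total*gamma_j
# [+ pleiotropy alpha_j] on Y), mediator-specific instruments (delta_j on M,
# b2*delta_j on Y, null on X), and outcome-specific instruments (direct
# effect on Y only). The mediator set identifies b2 and the outcome set makes
# reverse-direction MR testable; all three summary tables share the full SNP
# panel.

#' Define the ground truth of a simulated mediation triplet
#'
#' @param theta_direct direct exposure-outcome effect (default 0.08).
#' @param b1 exposure-mediator effect (default 0.3).
#' @param b2 mediator-outcome effect (default 0.4). The total effect is
#'   `theta_total = theta_direct + b1 * b2` (0.2 under the defaults, giving a
#'   true mediated proportion of 60%).
#' @param n_exp,n_med,n_out GWAS sample sizes (>= 100), default 50000.
#' @param J instruments per trait (>= 3), default 100.
#' @param maf_range minor-allele-frequency interval within (0, 0.5],
#'   default c(0.1, 0.5).
#' @param effect_sd SD of true per-SNP instrument effects, default 0.05.
#' @param f_target instrument effects are drawn from N(0, effect_sd^2)
#'   truncated so the true per-SNP F = (effect/se)^2 exceeds this value
#'   (default 10), so generated instruments are strong by construction.
#' @param pleiotropy list: `list(type = "none")`,
#'   `list(type = "balanced", sd = )` (exposure-SNP effects on the outcome
#'   get alpha_j ~ N(0, sd^2)) or `list(type = "directional", mean = , sd = )`.
#' @param ld_blocks list of `c(size, r2)` pairs; block k appends `size - 1`
#'   satellite SNPs in LD r2 with the k-th exposure index SNP (satellite true
#'   betas attenuate by r = sqrt(r2), the expectation for an LD-tagged
#'   marginal effect).
#' @param noise logical; FALSE yields the exact-identification limit
#'   (observed betas equal the true effects; analytic SEs are still written).
#' @param outcome_binary treat the outcome trait as binary (betas interpreted
#'   as log odds ratios under the same noise model at an effective n; an
#'   approximation).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(theta_direct = 0.08, b1 = 0.3, b2 = 0.4,
                      n_exp = 50000, n_med = 50000, n_out = 50000,
                      J = 100, maf_range = c(0.1, 0.5),
                      effect_sd = 0.05, f_target = 10,
                      pleiotropy = list(type = "none"),
                      ld_blocks = list(), noise = TRUE,
                      outcome_binary = FALSE, seed = 1L) {
  if (any(c(n_exp, n_med, n_out) < 100)) abort("sample sizes must be >= 100", "mrmediate_bad_input")
  if (J < 3) abort("J must be >= 3", "mrmediate_bad_input")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must be an interval within (0, 0.5]", "mrmediate_bad_input")
  }
  if (!pleiotropy$type %in% c("none", "balanced", "directional")) {
    abort("pleiotropy type must be none, balanced or directional", "mrmediate_bad_input")
  }
  if (length(ld_blocks) > J) abort("more LD blocks than exposure index SNPs", "mrmediate_bad_input")
  for (b in ld_blocks) {
    if (length(b) != 2 || b[1] < 2 || b[2] < 0 || b[2] > 1) {
      abort("each ld_block must be c(size >= 2, r2 in [0, 1])", "mrmediate_bad_input")
    }
  }
  structure(
    list(
      theta_direct = theta_direct, b1 = b1, b2 = b2,
      theta_total = theta_direct + b1 * b2,
      n_exp = n_exp, n_med = n_med, n_out = n_out, J = as.integer(J),
      maf_range = maf_range, effect_sd = effect_sd, f_target = f_target,
      pleiotropy = pleiotropy, ld_blocks = ld_blocks,
      noise = isTRUE(noise), outcome_binary = isTRUE(outcome_binary),
      seed = as.integer(seed)
    ),
    class = "sim_truth"
  )
}

# Truncated-normal draw: |effect| large enough that (effect/se)^2 > f_target.
#' @keywords internal
draw_instrument_effects <- function(se, effect_sd, f_target) {
  thr <- sqrt(f_target) * se
  u <- stats::runif(length(se))
  lower <- stats::pnorm(thr / effect_sd)
  q <- stats::qnorm(pmin(lower + u * (1 - lower), 1 - 1e-16))
  mag <- effect_sd * q
  # pathological case (threshold far beyond effect_sd): fall back just above it
  bad <- !is.finite(mag)
  mag[bad] <- thr[bad] * (1 + 0.1 * u[bad])
  mag * sample(c(-1, 1), length(se), replace = TRUE)
}

#' Simulate a mediation triplet of GWAS summary-statistics tables
#'
#' Generates exposure, mediator and outcome [sumstats] sharing one SNP panel,
#' plus the block-diagonal [ld_matrix], from a [sim_truth]. Fully
#' reproducible: identical seeds give identical objects (and identical files
#' once written). The caller's RNG state is preserved.
#'
#' @param truth a [sim_truth].
#' @return list with elements `exposure`, `mediator`, `outcome` ([sumstats]),
#'   `ld` ([ld_matrix]), `truth`, and `panel` — a data.frame of every SNP's
#'   role (`exposure`/`mediator`/`outcome`/`satellite`), block id and true
#'   per-trait effects, for recovery tests.
#' @export
simulate_triplet <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(truth$seed, simulate_triplet_impl(truth))
}

#' @keywords internal
simulate_triplet_impl <- function(truth) {
  J <- truth$J
  n_loci <- 3L * J
  roles <- rep(c("exposure", "mediator", "outcome"), each = J)
  maf <- stats::runif(n_loci, truth$maf_range[1], truth$maf_range[2])
  se_of <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

  # true per-locus instrument effects on their own trait
  own_n <- c(exposure = truth$n_exp, mediator = truth$n_med, outcome = truth$n_out)
  own_se <- se_of(own_n[roles], maf)
  eff <- draw_instrument_effects(own_se, truth$effect_sd, truth$f_target)

  gamma <- ifelse(roles == "exposure", eff, 0)
  delta <- ifelse(roles == "mediator", eff, 0)
  xi <- ifelse(roles == "outcome", eff, 0)

  alpha <- rep(0, n_loci)
  pl <- truth$pleiotropy
  if (pl$type == "balanced") {
    alpha[roles == "exposure"] <- stats::rnorm(J, 0, pl$sd)
  } else if (pl$type == "directional") {
    alpha[roles == "exposure"] <- stats::rnorm(J, pl$mean, pl$sd)
  }

  # pleiotropic effects are oriented to the exposure-increasing allele:
  # "directional" is only meaningful relative to the orientation the
  # estimators use, and arbitrary allele coding would otherwise symmetrize it
  true_exp <- gamma
  true_med <- truth$b1 * gamma + delta
  true_out <- truth$theta_total * gamma + sign(gamma) * alpha +
    truth$b2 * delta + xi

  # positions: loci >= 25 Mb apart (beyond any clumping window), cycling
  # chromosomes 1..22; satellites sit within 1 kb steps of their index SNP
  chrom <- as.character(((seq_len(n_loci) - 1L) %% 22L) + 1L)
  pos <- 1e6 + ((seq_len(n_loci) - 1L) %/% 22L) * 25e6

  # non-palindromic allele pairs only, so harmonization is lossless
  pairs <- c("AG", "AC", "GA", "GT", "CA", "CT", "TG", "TC")
  alle <- pairs[sample.int(8L, n_loci, replace = TRUE)]

  panel <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(n_loci)),
    chrom = chrom, pos = pos,
    effect_allele = substr(alle, 1, 1), other_allele = substr(alle, 2, 2),
    maf = maf, role = roles, block = NA_integer_,
    true_exp = true_exp, true_med = true_med, true_out = true_out,
    stringsAsFactors = FALSE
  )

  # LD blocks: satellites of the k-th exposure index SNP; true betas
  # attenuate by r = sqrt(r2) (expected LD-tagged marginal effect)
  blocks <- truth$ld_blocks
  if (length(blocks) > 0) {
    sat_rows <- list()
    for (k in seq_along(blocks)) {
      size <- as.integer(blocks[[k]][1])
      r2 <- blocks[[k]][2]
      r <- sqrt(r2)
      idx <- panel[k, ]  # k-th exposure index SNP
      panel$block[k] <- k
      n_sat <- size - 1L
      sat <- idx[rep(1L, n_sat), ]
      sat$snp_id <- sprintf("%s_s%02d", idx$snp_id, seq_len(n_sat))
      sat$pos <- idx$pos + 1000 * seq_len(n_sat)
      sat$maf <- idx$maf
      sat$role <- "satellite"
      sat$block <- k
      sat$true_exp <- r * idx$true_exp
      sat$true_med <- r * idx$true_med
      sat$true_out <- r * idx$true_out
      sat_rows[[k]] <- sat
    }
    panel <- rbind(panel, do.call(rbind, sat_rows))
    rownames(panel) <- NULL
  }

  m <- nrow(panel)
  se_exp <- se_of(truth$n_exp, panel$maf)
  se_med <- se_of(truth$n_med, panel$maf)
  se_out <- se_of(truth$n_out, panel$maf)
  noise <- if (truth$noise) 1 else 0
  beta_exp <- panel$true_exp + noise * stats::rnorm(m, 0, se_exp)
  beta_med <- panel$true_med + noise * stats::rnorm(m, 0, se_med)
  beta_out <- panel$true_out + noise * stats::rnorm(m, 0, se_out)

  make_ss <- function(beta, se, n, trait_id, trait_type) {
    sumstats(data.frame(
      snp_id = panel$snp_id, chrom = panel$chrom, pos = panel$pos,
      effect_allele = panel$effect_allele, other_allele = panel$other_allele,
      eaf = panel$maf, beta = beta, se = se,
      pval = two_sided_p(beta / se), n = n,
      stringsAsFactors = FALSE
    ), trait_id = trait_id, trait_type = trait_type)
  }

  r2_mat <- diag(m)
  dimnames(r2_mat) <- list(panel$snp_id, panel$snp_id)
  if (length(blocks) > 0) {
    for (k in seq_along(blocks)) {
      members <- panel$snp_id[!is.na(panel$block) & panel$block == k]
      r2_mat[members, members] <- blocks[[k]][2]
      for (s in members) r2_mat[s, s] <- 1
    }
  }

  list(
    exposure = make_ss(beta_exp, se_exp, truth$n_exp, "sim_exposure", "continuous"),
    mediator = make_ss(beta_med, se_med, truth$n_med, "sim_mediator", "continuous"),
    outcome = make_ss(beta_out, se_out, truth$n_out, "sim_outcome",
                      if (truth$outcome_binary) "binary" else "continuous"),
    ld = ld_matrix(r2_mat),
    truth = truth,
    panel = panel
  )
}

#' Serialize the ground truth of a simulation
#'
#' @param truth a [sim_truth].
#' @param paths optional named character vector of generated file paths to
#'   record alongside the parameters.
#' @return Named list of every true parameter (including the derived
#'   `theta_total`), suitable for YAML serialization.
#' @export
truth_report <- function(truth, paths = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  rep <- unclass(truth)
  rep$ld_blocks <- lapply(rep$ld_blocks, as.numeric)
  rep$maf_range <- as.numeric(rep$maf_range)
  if (!is.null(paths)) rep$paths <- as.list(paths)
  rep
}

#' Write a truth report to a YAML file
#' @param truth a [sim_truth].
#' @param path output path.
#' @param paths optional generated-file paths to record.
#' @return `path`, invisibly.
#' @export
write_truth_report <- function(truth, path, paths = NULL) {
  yaml::write_yaml(truth_report(truth, paths), path, precision = 15)
  invisible(path)
}

#' Read a truth report back into a sim_truth
#' @param path YAML path written by [write_truth_report()].
#' @return A [sim_truth].
#' @export
read_truth_report <- function(path) {
  rep <- yaml::read_yaml(path)
  tr <- sim_truth(
    theta_direct = rep$theta_direct, b1 = rep$b1, b2 = rep$b2,
    n_exp = rep$n_exp, n_med = rep$n_med, n_out = rep$n_out, J = rep$J,
    maf_range = unlist(rep$maf_range), effect_sd = rep$effect_sd,
    f_target = rep$f_target, pleiotropy = rep$pleiotropy,
    ld_blocks = rep$ld_blocks, noise = rep$noise,
    outcome_binary = rep$outcome_binary, seed = rep$seed
  )
  if (abs(tr$theta_total - rep$theta_total) > 1e-12) {
    abort("truth report inconsistent: theta_total != theta_direct + b1*b2",
          "mrmediate_bad_input")
  }
  tr
}
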