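---
title: "Two-sample MR and two-step mediation: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR and two-step mediation: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample MR treats each genetic instrument $j$ as delivering a noisy ratio
estimate of a causal effect. With summary associations
$\hat\beta_{Xj} \sim N(\beta_{Xj}, \sigma_{Xj}^2)$ from the exposure GWAS and
$\hat\beta_{Yj} \sim N(\beta_{Yj}, \sigma_{Yj}^2)$ from the outcome GWAS, a
valid instrument satisfies $\beta_{Yj} = \theta\,\beta_{Xj}$, so the Wald
ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect $\theta$.
The estimators differ in how they pool ratios and what they assume about
invalid instruments:

- **IVW**: weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$ through
  the origin, weights $1/\sigma_Y^2$. Consistent when all instruments are
  valid. Our default is the *multiplicative random effects* variant: the
  analytic SE is scaled by $\max\{1, \sqrt{Q/(J-1)}\}$, so unmodeled
  heterogeneity widens the interval but can never shrink it below the
  fixed-effects SE. P-values are normal.
- **MR-Egger**: the same regression *with* an intercept, after orienting all
  rows to $\hat\beta_X \ge 0$. The slope is a pleiotropy-adjusted causal
  estimate (consistent under the InSIDE assumption); the intercept estimates
  average directional pleiotropy. Coefficient SEs scale with the residual
  dispersion $\sqrt{Q'/(J-2)}$ and inference uses a $t_{J-2}$ reference.
  We deliberately do **not** floor the Egger dispersion at 1 (unlike IVW):
  the un-floored weighted-LS form is exactly $t$-calibrated, which the
  intercept test's type-I error depends on, and it is what the standard
  two-sample MR toolchain reports. With the floor, the intercept test would
  be conservative (empirical size ≈ 3.5–4% at $J = 20$).
- **Weighted median**: the ratio at cumulative weight 0.5, interpolated along
  the sorted ratios with normalized weights $1/\mathrm{se}(r_j)^2$, where
  $\mathrm{se}(r_j) = \sigma_{Yj}/|\hat\beta_{Xj}|$ (first-order delta).
  Consistent when instruments carrying ≥50% of the weight are valid. SE by
  parametric bootstrap.
- **Simple / weighted mode**: the argmax of a normal-kernel density of the
  ratios, bandwidth $\phi \cdot 0.9\,\min(\mathrm{sd}, \mathrm{MAD})\,
  J^{-1/5}$ (MAD on the normal-consistent scale), evaluated on a 512-point
  grid spanning the ratio range ± 3 bandwidths. Weights are uniform (simple)
  or inverse-variance (weighted). Consistent when the largest cluster of
  ratios is the valid one. If the spread is degenerate (MAD or SD zero) the
  estimate is the ratio value carrying the most weight, which makes the
  noise-free limit exact. SE by parametric bootstrap.

All bootstrap SEs (default 1000 replicates) are seeded and restore the
caller's RNG state, so pipeline outputs are bit-reproducible.

## Instrument screening defaults

| parameter | default | meaning |
|---|---|---|
| `p_max` | 5e-5 (inclusive) | exposure-association threshold for candidate instruments, the usual relaxation for molecular phenotypes where genome-wide 5e-8 leaves too few SNPs |
| `clump_r2` | 0.01 | retained instruments are pairwise $r^2 < 0.01$ within the window |
| `clump_kb` | 10,000 kb | physical clumping window (distance ≤ 10 Mb counts as within; greedy by ascending p-value, ties broken lexicographically by SNP id so results are order-invariant) |
| `f_min` | 10 (exclusive) | weak-instrument cut on $F = (\hat\beta_X/\sigma_X)^2$; instruments are retained only with $F > 10$ |
| `proxy_r2_min` | 0.8 (inclusive) | minimum LD for substituting a proxy SNP when the target is absent from the outcome |
| `alpha` | 0.05 | significance level for every screening gate |

$F = (\beta/\mathrm{se})^2$ — the square of the marginal Wald $z$ — is used
rather than the $2\,\mathrm{MAF}(1-\mathrm{MAF})\,n R^2$ form because it needs
no sample-size or frequency fields and equals the same quantity in
expectation for a standardized trait. SNPs absent from the LD matrix are
retained with an audit flag `no_ld_info` rather than dropped: silently
dropping them would bias screens toward sparse LD tables, and the audit trail
makes the choice visible.

Palindromic (A/T, C/G) SNPs are always excluded during harmonization; no
allele-frequency rescue (e.g. the common "MAF < 0.42" rule) is attempted,
because strand cannot be resolved from the alleles alone and the screening
cascade is meant to be conservative. Proxy effect sizes are taken as-is with
no $r^2$ attenuation correction; a direct match always beats a proxy.

## The screening cascade

Per exposure, the gates are applied in order: IVW significance, direction
consistency of all five estimates (equivalently all ORs on the same side
of 1), Egger-intercept p > α, IVW Cochran-Q p > α. The significance gate
defaults to the *nominal* IVW p-value with the BH-FDR-adjusted p-value
reported alongside (`screen_on = "fdr"` switches the gate); the two
conventions coexist in practice and the choice is exposed rather than
hidden. A reverse-direction MR (outcome as exposure, its own instruments at
the same thresholds) is recorded descriptively — `yes`/`no`/`untestable` —
and never excludes an exposure by default, since a reverse signal may reflect
the outcome's own genetics rather than a failed assumption.

## Mediation decomposition

For an exposure X that passed the screen, a mediator M and outcome Y, three
independent MR legs give $\hat b_1$ (X→M), $\hat b_2$ (M→Y) and the total
effect $\hat\theta$ (X→Y). Then

$$\mathrm{ME} = \hat b_1 \hat b_2, \qquad
\mathrm{se(ME)} = \sqrt{\hat b_1^2 s_2^2 + \hat b_2^2 s_1^2}, \qquad
\mathrm{MP} = 100\,\mathrm{ME}/\hat\theta\%,$$

with the direct effect $\hat\theta - \mathrm{ME}$ and a first-order ratio
delta SE for MP. Covariance terms are zero because the three legs come from
non-overlapping samples. Everything is signed: a mediated effect opposing
the total effect yields a negative MP, and no clamping or absolute value is
applied — sign conventions in published mediation tables are frequently
inconsistent, and recomputing from first principles is the only auditable
choice. Pairs enter the decomposition when the mediator-outcome and
exposure-mediator legs are both significant at α; the "meaningful" flag is a
swappable predicate (default: both path p-values < α) because published
pipelines rarely state this rule precisely.

## The synthetic generator

`simulate_triplet()` emulates three non-overlapping GWAS cohorts measuring
X, M and Y under the linear structural model

$$M = b_1 X + \varepsilon_M, \qquad
Y = \theta_{direct} X + b_2 M + \varepsilon_Y, \qquad
\theta_{total} = \theta_{direct} + b_1 b_2.$$

Summary statistics are generated directly — no individual-level genotypes —
because the pipeline consumes only summaries and direct generation makes the
noise model checkable: each observed beta is the true marginal effect plus
$N(0, \mathrm{se}^2)$ noise with the analytic
$\mathrm{se} = 1/\sqrt{2 n \,\mathrm{maf}(1-\mathrm{maf})}$ of a
standardized-trait regression. The binary-outcome mode reinterprets the same
noise model on the log-odds scale at an effective $n$; this is an
approximation and is documented as such.

Three disjoint sets of $J$ index SNPs are drawn: exposure-specific
instruments ($\gamma_j$ on X, propagating $b_1\gamma_j$ to M and
$\theta_{total}\gamma_j$ to Y), mediator-specific instruments ($\delta_j$ on
M, $b_2\delta_j$ on Y, null on X), and outcome-specific instruments (direct
effects on Y only). The mediator set is what identifies $b_2$: instruments
for X are *invalid* instruments for M (their Wald ratio against Y is
$\theta_{total}/b_1$, not $b_2$), so a generator with only exposure SNPs
could not validate the mediation stage at all. The outcome set gives the
reverse-direction MR something real to test. A side effect worth knowing:
when M is analyzed as an exposure, a few X-SNPs can leak past the selection
threshold and contribute ratios of $\theta_{total}/b_1$ — genuine
heterogeneity that the Q gate may flag. Their IVW weight share is below 1% at
the default settings, so estimates are essentially unbiased, but screening
verdicts for the mediator-as-exposure leg can legitimately be `excluded`.

Other generator conventions:

- Instrument effects are drawn from $N(0, 0.05^2)$ truncated so the true
  per-SNP $F$ exceeds 10 — instruments are strong by construction, matching
  the post-filtering regime the estimators actually see.
- Pleiotropic effects $\alpha_j$ (balanced or directional) are oriented to
  the exposure-increasing allele; "directional" is only meaningful relative
  to the orientation the estimators use, and arbitrary allele coding would
  otherwise symmetrize it away.
- LD blocks append satellite SNPs whose true betas attenuate by
  $r = \sqrt{r^2}$ (the expectation for an LD-tagged marginal effect); the
  block $r^2$ is written to the LD matrix so clumping can be validated
  (one retained SNP per block).
- Allele pairs are sampled from the eight non-palindromic pairs so
  harmonization is lossless; index loci are ≥ 25 Mb apart (beyond any
  clumping window) cycling chromosomes 1–22.
- Defaults ($\theta_{direct} = 0.08$, $b_1 = 0.3$, $b_2 = 0.4$, hence
  $\theta_{total} = 0.2$ and true MP 60%; $J = 100$; $n = 50{,}000$;
  maf ∈ [0.1, 0.5]) define the reference recovery conditions used by the
  acceptance checks.

What the generator does *not* emulate: realistic genome-wide LD maps,
population stratification, sample overlap between cohorts, case-control
ascertainment, or winner's-curse selection from an external discovery scan.
Passing recovery tests therefore demonstrates the correctness of the
estimators and plumbing under the stated model — not robustness to every
pathology of real GWAS data.

## Calibration design

The type-I calibration checks (Egger-intercept rejection rate, mean
Cochran-Q) run under the *global null* — all causal effects zero, no
pleiotropy — at $J = 20$, $n = 20{,}000$, 1000 replicates. The null is the
only configuration in which Q (with the conventional $1/\sigma_Y^2$ weights)
has an exact $\chi^2_{J-1}$ reference: with a nonzero causal effect,
measurement error in $\hat\beta_X$ (the NOME violation) genuinely
over-disperses Q by a factor $\approx 1 + \theta^2\sigma_X^2/\sigma_Y^2$,
which is a property of the statistic, not a bug. Because replicate instrument
counts vary slightly after selection, calibration is assessed on $Q/df$,
whose expectation is exactly 1 under the null. Parameter recovery
(IVW mean within 0.02 of $\theta_{total} = 0.2$, 95%-CI coverage in
[92%, 97%], mean estimated MP within 5 points of 60%) uses 500 replicates of
the full select → clump → harmonize → filter → IVW pipeline; these problem
sizes keep the whole suite comfortably within a coffee break on one CPU
while leaving Monte-Carlo error well inside the asserted bands.

## Numerical and degenerate-input choices

- Exact-fit regressions (zero residual) give SE 0; p-values are clamped to
  the smallest positive double rather than 0 to respect the $(0,1]$ contract.
- `wald_ratio` refuses $\hat\beta_X = 0$; the generator's truncation makes
  this a measure-zero event in simulated instruments.
- Duplicate SNP ids in one table keep the smallest p-value (deterministic,
  favors the stronger signal); p-value ties in clumping break
  lexicographically.
- A mediated proportion is undefined at total effect 0 and raises a typed
  error rather than returning ±Inf.
- On-disk numbers are written with 10 significant digits; reruns with
  identical configs are byte-identical.

## Known limitations

- No MR-PRESSO outlier removal, Steiger directionality filtering,
  contamination-mixture or multivariable/network MR — the screening cascade
  and the product-of-coefficients decomposition are the implemented scope.
- LD is consumed, never computed: clumping and proxy search require
  user-supplied LD/proxy tables (from e.g. a 1000 Genomes reference panel).
- The mediation SE ignores any sample overlap between legs; with overlapping
  cohorts the Sobel SE would be anti-conservative.
- The weighted-median and mode SEs are bootstrap-based and therefore carry
  seed-dependent Monte-Carlo error of order $1/\sqrt{n_{boot}}$.
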