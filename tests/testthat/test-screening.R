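# FDR adjustment, the screening cascade gates, and the mediation
# decomposition.

test_that("BH adjustment matches hand-applied step-up values", {
  # step-up by hand: sorted p * m / rank = (.04,.04,.04,.04) after monotonicity
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)               # m = 1 unchanged
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))     # boundary
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 0.986)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 0)), class = "mrmediate_bad_input")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "mrmediate_bad_input")
})

test_that("an exposure passing every gate is classified by effect direction", {
  pr <- list(
    up = fake_pair(ests = c(0.15, 0.2, 0.12, 0.3, 0.25)),
    down = fake_pair(ests = c(-0.15, -0.2, -0.12, -0.3, -0.25))
  )
  sc <- screen_total_effects(pr)
  expect_equal(sc$verdict, c("risk", "protective"))
  expect_true(all(sc$direction_consistent))
  expect_equal(sc$reason, c("", ""))
})

test_that("each gate excludes on its own: direction, pleiotropy, heterogeneity, significance", {
  pr <- list(
    mixed = fake_pair(ests = c(0.18, -0.1, 0.1, 0.26, 0.18)),     # OR straddles 1
    pleio = fake_pair(ests = rep(0.2, 5), int_p = 0.01),
    het = fake_pair(ests = rep(0.2, 5), q_p = 0.01),
    nonsig = fake_pair(ests = rep(0.2, 5), ivw_p = 0.2)
  )
  sc <- screen_total_effects(pr)
  expect_equal(sc$verdict, rep("excluded", 4))
  expect_match(sc$reason[sc$exposure_id == "mixed"], "direction")
  expect_match(sc$reason[sc$exposure_id == "pleio"], "pleiotropy")
  expect_match(sc$reason[sc$exposure_id == "het"], "heterogeneity")
  expect_match(sc$reason[sc$exposure_id == "nonsig"], "significance")
})

test_that("screen_on = fdr gates on the adjusted p-value", {
  pr <- list(
    a = fake_pair(ests = rep(0.2, 5), ivw_p = 0.04),
    b = fake_pair(ests = rep(0.2, 5), ivw_p = 0.9),
    c = fake_pair(ests = rep(0.2, 5), ivw_p = 0.9)
  )
  nominal <- screen_total_effects(pr, screen_on = "nominal")
  fdr <- screen_total_effects(pr, screen_on = "fdr")
  expect_equal(nominal$verdict[1], "risk")       # 0.04 < 0.05 nominally
  expect_equal(fdr$verdict[1], "excluded")       # BH-adjusted 0.12 fails
  expect_equal(fdr$fdr_pval[1], 0.12)
})

test_that("screening is deterministic and reverse flag is descriptive only", {
  pr <- list(
    x = fake_pair(ests = rep(0.2, 5), reverse_pval = 0.01),  # reverse significant
    y = fake_pair(ests = rep(0.2, 5), reverse_pval = 0.5),
    z = fake_pair(ests = rep(0.2, 5))
  )
  s1 <- screen_total_effects(pr)
  s2 <- screen_total_effects(pr)
  expect_identical(s1, s2)
  expect_equal(s1$reverse_ok, c("no", "yes", "untestable"))
  expect_equal(s1$verdict, rep("risk", 3))  # reverse never excludes by default
})

test_that("missing method results exclude that exposure and spare the rest", {
  good <- fake_pair(ests = rep(0.2, 5))
  bad <- fake_pair(ests = rep(0.2, 5))
  bad$results <- bad$results[bad$results$method != "weighted_mode", ]
  sc <- screen_total_effects(list(ok = good, broken = bad))
  expect_equal(sc$verdict[sc$exposure_id == "ok"], "risk")
  expect_equal(sc$verdict[sc$exposure_id == "broken"], "excluded")
  expect_match(sc$reason[sc$exposure_id == "broken"], "weighted_mode")
})

test_that("two-step mediation arithmetic and delta-method SEs", {
  m <- two_step_mediation(
    beta1 = list(estimate = 0.2, se = 0.1),
    beta2 = list(estimate = 0.3, se = 0.1),
    total = list(estimate = 0.3, se = 0.05)
  )
  expect_equal(m$me, 0.06)
  expect_equal(m$mp_pct, 20)
  expect_equal(m$direct, 0.24)
  expect_equal(m$me_se, sqrt(0.2^2 * 0.1^2 + 0.3^2 * 0.1^2), tolerance = 1e-12)
  expect_equal(m$me_se, 0.036055512, tolerance = 1e-7)
  # zero mediated path
  m0 <- two_step_mediation(list(estimate = 0, se = 0.1),
                           list(estimate = 0.3, se = 0.1),
                           list(estimate = 0.3, se = 0.05))
  expect_equal(m0$me, 0)
  expect_equal(m0$mp_pct, 0)
  # undefined proportion
  expect_error(two_step_mediation(list(estimate = 0.1, se = 0.1),
                                  list(estimate = 0.1, se = 0.1),
                                  list(estimate = 0, se = 0.05)),
               class = "mrmediate_undefined_proportion")
})

test_that("mediation identities hold to machine precision and MP is signed", {
  set.seed(19)
  for (i in 1:20) {
    b1 <- rnorm(1); b2 <- rnorm(1); tot <- rnorm(1)
    if (tot == 0) next
    m <- two_step_mediation(list(estimate = b1, se = 0.1),
                            list(estimate = b2, se = 0.1),
                            list(estimate = tot, se = 0.1))
    expect_identical(m$me, b1 * b2)
    expect_equal(m$direct + m$me, m$total, tolerance = 1e-15)
    expect_equal(m$mp_pct / 100 * m$total, m$me, tolerance = 1e-15)
  }
  # a negative mediated proportion is reported as-is, never clamped
  m <- two_step_mediation(list(estimate = -0.2, se = 0.1),
                          list(estimate = 0.3, se = 0.1),
                          list(estimate = 0.3, se = 0.05))
  expect_equal(m$mp_pct, -20)
})

test_that("assemble_pairs intersects screened exposures, significant mediators and paths", {
  screen <- data.frame(
    exposure_id = c("x1", "x2", "x3", "x4"),
    verdict = c("risk", "protective", "risk", "excluded"),
    stringsAsFactors = FALSE
  )
  total <- data.frame(exposure_id = paste0("x", 1:4), estimate = 0.3, se = 0.05,
                      pval = 0.01, stringsAsFactors = FALSE)
  med_out <- data.frame(mediator_id = c("m1", "m2", "m3"),
                        estimate = c(0.4, -0.2, 0.1),
                        se = 0.05, pval = c(0.001, 0.02, 0.4),
                        stringsAsFactors = FALSE)  # m3 not significant
  combos <- expand.grid(exposure_id = paste0("x", 1:3), mediator_id = c("m1", "m2"),
                        stringsAsFactors = FALSE)
  exp_med <- data.frame(combos, estimate = 0.25, se = 0.04,
                        pval = c(0.01, 0.01, 0.3, 0.01, 0.01, 0.3),
                        stringsAsFactors = FALSE)
  pairs <- assemble_pairs(screen, total, exp_med, med_out, outcome_id = "Y")
  expect_equal(nrow(pairs), 4)  # x3 path non-significant twice; m3 gated out; x4 screened out
  expect_false(any(pairs$exposure_id == "x4"))
  expect_false(any(pairs$mediator_id == "m3"))
  expect_true(all(pairs$meaningful))
  # identities on every emitted row
  expect_equal(pairs$me, pairs$beta1 * pairs$beta2, tolerance = 1e-15)
  expect_equal(pairs$direct + pairs$me, pairs$total, tolerance = 1e-15)
  expect_equal(pairs$mp_pct / 100 * pairs$total, pairs$me, tolerance = 1e-15)
  # no significant mediator -> empty result with full schema
  none <- assemble_pairs(screen, total, exp_med,
                         transform(med_out, pval = 0.9), outcome_id = "Y")
  expect_equal(nrow(none), 0)
  expect_true(all(c("exposure_id", "mp_pct", "meaningful") %in% names(none)))
})

test_that("relaxed entry gates assemble non-significant paths but flag them", {
  screen <- data.frame(exposure_id = "x1", verdict = "risk", stringsAsFactors = FALSE)
  total <- data.frame(exposure_id = "x1", estimate = 0.3, se = 0.05, pval = 0.01,
                      stringsAsFactors = FALSE)
  med_out <- data.frame(mediator_id = "m1", estimate = 0.05, se = 0.05, pval = 0.6,
                        stringsAsFactors = FALSE)  # b2 null
  exp_med <- data.frame(exposure_id = "x1", mediator_id = "m1", estimate = 0.25,
                        se = 0.04, pval = 0.001, stringsAsFactors = FALSE)  # b1 significant
  pairs <- assemble_pairs(screen, total, exp_med, med_out,
                          require_mediator = FALSE, require_path = FALSE)
  expect_equal(nrow(pairs), 1)
  expect_false(pairs$meaningful)
})
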