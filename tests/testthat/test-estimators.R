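# The five causal estimators against independent oracles and their
# equivariance properties.

test_that("Wald ratio and its delta-method SE", {
  wr <- wald_ratio(0.10, 0.01, 0.05, 0.02)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.2)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$ratio, 0)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), class = "mrmediate_bad_input")
})

test_that("single-SNP IVW (fixed) equals the Wald ratio exactly", {
  h <- make_hset(bx = 0.1, by = 0.05, sx = 0.01, sy = 0.02)
  fit <- mr_ivw(h, "fixed")
  expect_equal(fit$estimate, 0.5)
  expect_equal(fit$se, 0.2)
  expect_error(mr_ivw(h, "mre"), class = "mrmediate_insufficient_snps")
})

test_that("consensus case: identical ratios give the ratio, Q = 0, fixed = mre", {
  h <- make_hset(bx = c(0.1, 0.2, 0.4), by = c(0.03, 0.06, 0.12),
                 sy = c(0.01, 0.02, 0.05))
  fit_f <- mr_ivw(h, "fixed")
  fit_m <- mr_ivw(h, "mre")
  expect_equal(fit_f$estimate, 0.3)
  expect_equal(attr(fit_f, "Q"), 0)
  expect_equal(fit_m$se, fit_f$se)
})

test_that("IVW equals an independent weighted-regression-through-origin oracle", {
  bx <- c(0.1, 0.2, 0.3)
  by <- c(0.02, 0.05, 0.09)
  sy <- c(0.01, 0.01, 0.01)
  h <- make_hset(bx = bx, by = by, sy = sy)
  fit <- mr_ivw(h, "fixed")
  # closed form: sum(w x y) / sum(w x^2) with w = 1/sy^2
  expect_equal(fit$estimate, 0.039 / 0.14, tolerance = 1e-12)
  oracle <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_equal(fit$estimate, unname(coef(oracle)), tolerance = 1e-10)
  expect_equal(fit$se, sqrt(1 / sum(bx^2 / sy^2)), tolerance = 1e-12)
  # mre variant inflates by sqrt(Q/(J-1)) with the fixed SE as a floor
  q <- sum((by - fit$estimate * bx)^2 / sy^2)
  expect_equal(mr_ivw(h, "mre")$se, fit$se * max(1, sqrt(q / 2)), tolerance = 1e-12)
})

test_that("MR-Egger matches weighted least squares with intercept (4-point fixture)", {
  bx <- c(0.08, 0.15, 0.22, 0.3)
  by <- c(0.03, 0.05, 0.08, 0.1)
  sy <- c(0.01, 0.015, 0.012, 0.02)
  h <- make_hset(bx = bx, by = by, sy = sy)
  fit <- mr_egger(h)
  oracle <- summary(lm(by ~ bx, weights = 1 / sy^2))
  expect_equal(fit$slope$estimate, oracle$coefficients["bx", "Estimate"], tolerance = 1e-10)
  expect_equal(fit$slope$se, oracle$coefficients["bx", "Std. Error"], tolerance = 1e-10)
  expect_equal(fit$slope$pval, oracle$coefficients["bx", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(fit$intercept$estimate, oracle$coefficients["(Intercept)", "Estimate"],
               tolerance = 1e-10)
  expect_equal(fit$intercept$se, oracle$coefficients["(Intercept)", "Std. Error"],
               tolerance = 1e-10)
  expect_equal(fit$intercept$pval, oracle$coefficients["(Intercept)", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("exact-fit Egger recovers intercept and slope with zero residual", {
  bx <- c(0.1, 0.2, 0.3, 0.5)
  by <- 0.02 + 0.4 * bx
  h <- make_hset(bx = bx, by = by)
  fit <- mr_egger(h)
  expect_equal(fit$slope$estimate, 0.4, tolerance = 1e-12)
  expect_equal(fit$intercept$estimate, 0.02, tolerance = 1e-12)
  expect_lt(attr(fit, "Q"), 1e-20)
  expect_error(mr_egger(make_hset(bx = c(0.1, 0.2), by = c(0.1, 0.2))),
               class = "mrmediate_insufficient_snps")
})

test_that("Egger orientation makes the fit invariant to per-row sign flips", {
  set.seed(3)
  bx <- rnorm(8, 0, 0.1)
  by <- 0.01 + 0.3 * bx + rnorm(8, 0, 0.01)
  sy <- runif(8, 0.005, 0.02)
  h1 <- make_hset(bx = bx, by = by, sy = sy)
  flip <- sample(c(-1, 1), 8, replace = TRUE)
  h2 <- make_hset(bx = flip * bx, by = flip * by, sy = sy)
  f1 <- mr_egger(h1)
  f2 <- mr_egger(h2)
  expect_equal(f2$slope$estimate, f1$slope$estimate, tolerance = 1e-12)
  expect_equal(f2$intercept$estimate, f1$intercept$estimate, tolerance = 1e-12)
})

test_that("weighted median: symmetric, breakdown, and brute-force oracle cases", {
  # equal weights, three ratios -> the middle one
  h <- make_hset(bx = c(1, 1, 1), by = c(0.1, 0.4, 0.9))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$estimate, 0.4)
  # dominant weight (>50%) pins the estimate near that SNP's ratio
  hd <- make_hset(bx = c(1, 1, 1), by = c(0.1, 0.4, 0.9),
                  sy = c(0.001, 1, 1))
  expect_equal(mr_weighted_median(hd, n_boot = 50, seed = 1)$estimate, 0.1,
               tolerance = 0.01)
  # 5-SNP unequal-weight fixture vs the independent interpolation oracle
  bx <- c(0.12, 0.2, 0.31, 0.15, 0.25)
  by <- c(0.05, 0.07, 0.1, 0.02, 0.12)
  sy <- c(0.01, 0.02, 0.015, 0.012, 0.03)
  h5 <- make_hset(bx = bx, by = by, sy = sy)
  fit <- mr_weighted_median(h5, n_boot = 50, seed = 1)
  expect_equal(fit$estimate,
               oracle_weighted_median(by / bx, (bx / sy)^2),
               tolerance = 1e-12)
  expect_error(mr_weighted_median(make_hset(bx = c(1, 1), by = c(1, 1))),
               class = "mrmediate_insufficient_snps")
})

test_that("mode estimators: dominant cluster wins; dense-grid oracle agreement", {
  h <- make_hset(bx = rep(1, 4), by = c(0.2, 0.2, 0.2, 5.0))
  fit <- mr_mode(h, n_boot = 50, seed = 1)
  expect_equal(fit$estimate, 0.2, tolerance = 0.05)
  # all ratios equal -> degenerate density returns that value exactly
  hc <- make_hset(bx = rep(1, 3), by = rep(0.7, 3))
  expect_equal(mr_mode(hc, n_boot = 10, seed = 1)$estimate, 0.7)
  # two clusters; weights favor the smaller cluster under weighted mode
  bx <- rep(1, 7)
  by <- c(0.1, 0.12, 0.11, 0.14, 0.5, 0.52, 0.51)
  sy <- c(rep(0.2, 4), rep(0.02, 3))
  h2 <- make_hset(bx = bx, by = by, sy = sy)
  simple <- mr_mode(h2, weighted = FALSE, n_boot = 10, seed = 1)
  weighted <- mr_mode(h2, weighted = TRUE, n_boot = 10, seed = 1)
  expect_lt(simple$estimate, 0.3)
  expect_gt(weighted$estimate, 0.3)
  # fine-grid brute-force density argmax oracle
  oracle_mode <- function(r, w, phi = 1) {
    w <- w / sum(w)
    bw <- phi * 0.9 * min(sd(r), mad(r)) * length(r)^(-0.2)
    grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 200001)
    dens <- sapply(seq_along(r), function(j) w[j] * dnorm(grid, r[j], bw))
    grid[which.max(rowSums(dens))]
  }
  grid_step <- (diff(range(by / bx)) + 6 * 0.9 * min(sd(by / bx), mad(by / bx)) *
                  7^(-0.2)) / 511
  expect_lt(abs(simple$estimate - oracle_mode(by / bx, rep(1, 7))), grid_step)
  expect_lt(abs(weighted$estimate - oracle_mode(by / bx, (bx / sy)^2)), grid_step)
})

test_that("sign and scale equivariance hold for every method", {
  set.seed(17)
  bx <- runif(6, 0.05, 0.3)
  by <- 0.25 * bx + rnorm(6, 0, 0.01)
  sx <- runif(6, 0.005, 0.01)
  sy <- runif(6, 0.005, 0.02)
  h <- make_hset(bx = bx, by = by, sx = sx, sy = sy)
  h_neg <- make_hset(bx = -bx, by = by, sx = sx, sy = sy)
  h_scaled <- make_hset(bx = 2 * bx, by = by, sx = sx, sy = sy)
  ests <- function(hh) c(
    ivw = mr_ivw(hh)$estimate,
    egger = mr_egger(hh)$slope$estimate,
    wm = mr_weighted_median(hh, n_boot = 20, seed = 2)$estimate,
    sm = mr_mode(hh, n_boot = 20, seed = 2)$estimate,
    wmode = mr_mode(hh, weighted = TRUE, n_boot = 20, seed = 2)$estimate
  )
  e <- ests(h)
  expect_equal(ests(h_neg), -e, tolerance = 1e-8)
  expect_equal(ests(h_scaled), e / 2, tolerance = 1e-8)
  # Egger intercept magnitude and test are invariant under negation (the
  # re-orientation flips its sign together with the outcome betas)
  expect_equal(abs(mr_egger(h_neg)$intercept$estimate),
               abs(mr_egger(h)$intercept$estimate), tolerance = 1e-12)
  expect_equal(mr_egger(h_neg)$intercept$pval, mr_egger(h)$intercept$pval,
               tolerance = 1e-12)
})

test_that("median and mode estimates always lie within the ratio range", {
  set.seed(23)
  for (i in 1:10) {
    j <- sample(3:12, 1)
    h <- make_hset(bx = runif(j, 0.05, 0.3), by = rnorm(j, 0.02, 0.05),
                   sy = runif(j, 0.005, 0.05))
    r <- h$data$beta_out / h$data$beta_exp
    for (est in c(mr_weighted_median(h, n_boot = 5, seed = i)$estimate,
                  mr_mode(h, n_boot = 5, seed = i)$estimate,
                  mr_mode(h, weighted = TRUE, n_boot = 5, seed = i)$estimate)) {
      expect_gte(est, min(r) - 1e-12)
      expect_lte(est, max(r) + 1e-12)
    }
  }
})

test_that("bootstrap SEs are reproducible under a fixed seed and leave the RNG alone", {
  h <- make_hset(bx = c(0.1, 0.2, 0.3, 0.15), by = c(0.03, 0.05, 0.1, 0.04))
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  f1 <- mr_weighted_median(h, n_boot = 200, seed = 42)
  f2 <- mr_weighted_median(h, n_boot = 200, seed = 42)
  after <- rnorm(1)
  expect_identical(f1$se, f2$se)
  expect_identical(before, after)  # caller RNG stream undisturbed
  expect_false(mr_weighted_median(h, n_boot = 200, seed = 43)$se == f1$se)
})

test_that("binary outcomes carry exponentiated OR fields; CI brackets the estimate", {
  h <- make_hset(bx = c(0.1, 0.2, 0.3), by = c(0.02, 0.05, 0.09),
                 outcome_type = "binary")
  res <- mr_all_methods(h, n_boot = 20, seed = 1)
  expect_equal(res$or_point, exp(res$estimate))
  expect_equal(res$or_low, exp(res$ci_low))
  expect_true(all(res$ci_low <= res$estimate & res$estimate <= res$ci_high))
  expect_setequal(res$method,
                  c("ivw", "egger", "weighted_median", "simple_mode", "weighted_mode"))
  # egger intercept travels on the egger row only
  expect_true(is.finite(res$intercept_pval[res$method == "egger"]))
  expect_true(all(is.na(res$intercept_pval[res$method != "egger"])))
})
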