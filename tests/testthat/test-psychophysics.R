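test_that("geometric series reproduces the published compound ranges", {
  am <- geometric_series(3.5e-9, 1.5, 12)
  expect_equal(signif(am[12], 2), 3.0e-7)
  gr <- geometric_series(5.8e-7, 1.5, 12)
  expect_equal(signif(gr[12], 2), 5.0e-5)
  expect_equal(geometric_series(2, 1, 5), rep(2, 5))
  expect_error(geometric_series(-1, 1.5, 12), "start")
  expect_error(geometric_series(1e-6, 0, 12), "ratio")
})

test_that("psychometric MLE recovers a noise-free threshold and beats the grid oracle", {
  conc <- geometric_series(1e-6, 1.5, 12)
  lc <- log10(conc)
  mu_true <- log10(1e-5)
  set.seed(2)
  p <- 0.25 + 0.75 * plogis(12 * (lc - mu_true))
  resp <- rep(round(p), each = 3)   # deterministic steep responses
  fit <- fit_psychometric(rep(conc, each = 3), resp, "detection")
  expect_lt(abs(fit$mu - mu_true), 0.05)
  expect_equal(fit$censor, "none")
  orc <- oracle_psy_grid(rep(lc, each = 3), resp, 0.25,
                         seq(min(lc), max(lc), 0.01), c(2, 4, 8, 16, 32))
  expect_lte(-fit$loglik, orc$nll + 1e-6)
  expect_lt(abs(fit$mu - orc$mu), 0.05)
})

test_that("degenerate response series are censored, not errors", {
  conc <- geometric_series(1e-6, 1.5, 12)
  all_correct <- fit_psychometric(conc, rep(1, 12), "detection")
  expect_equal(all_correct$censor, "low")
  expect_equal(all_correct$threshold, min(conc))
  set.seed(33)
  at_chance <- fit_psychometric(rep(conc, 3), rbinom(36, 1, 0.25), "detection")
  expect_equal(at_chance$censor, "high")
  all_no <- fit_psychometric(conc, rep(0, 12), "recognition")
  expect_equal(all_no$censor, "high")
  expect_error(fit_psychometric(conc[1:3], c(1, 1, 0)), ">= 4")
})

test_that("detection thresholds sit below recognition thresholds when simulated so", {
  conc <- geometric_series(1e-7, 1.5, 12)
  lc <- log10(conc)
  set.seed(14)
  diffs <- replicate(25, {
    mu <- runif(1, lc[4], lc[9])
    det <- rbinom(36, 1, 0.25 + 0.75 * plogis(8 * (rep(lc, 3) - (mu - 0.3))))
    rec <- rbinom(36, 1, plogis(8 * (rep(lc, 3) - mu)))
    f1 <- fit_psychometric(rep(conc, 3), det, "detection")
    f2 <- fit_psychometric(rep(conc, 3), rec, "recognition")
    f2$mu - f1$mu
  })
  expect_gt(mean(diffs > 0), 0.8)
  expect_gt(mean(diffs), 0.15)
})

test_that("threshold recovery meets the design precision over many series", {
  # pooled 12 steps x 3 repetitions at the study design
  conc <- geometric_series(1e-7, 1.5, 12)
  lc <- rep(log10(conc), 3)
  set.seed(90)
  err <- replicate(200, {
    mu <- runif(1, log10(conc[4]), log10(conc[9]))
    resp <- rbinom(36, 1, plogis(8 * (lc - mu)))
    fit_psychometric(rep(conc, 3), resp, "recognition")$mu - mu
  })
  expect_lt(median(abs(err)), 0.1)
})

test_that("Peirce's criterion matches the reference implementation and the classic example", {
  px <- bitterhap:::peirce_x2
  # frozen from an independent scipy-based reference implementation
  expect_equal(px(10, 1), 3.7498535593, tolerance = 1e-9)
  expect_equal(px(15, 1), 4.5008896592, tolerance = 1e-9)
  expect_equal(px(30, 1), 5.8268873817, tolerance = 1e-9)
  expect_equal(px(30, 2), 4.5180886629, tolerance = 1e-9)
  expect_equal(px(50, 1), 6.8214178507, tolerance = 1e-9)
  expect_equal(px(20, 3), 3.0852636029, tolerance = 1e-9)

  expect_true(all(peirce_outliers(rep(3.2, 10))))
  set.seed(4)
  x <- rnorm(30); x[13] <- x[13] + 8
  keep <- peirce_outliers(x)
  expect_equal(which(!keep), 13L)
  # idempotence on the cleaned sample
  expect_true(all(peirce_outliers(x[keep])))
  expect_warning(peirce_outliers(c(1, 2)), "fewer than 3")
})

test_that("intensity inversion reproduces a noise-free generating curve", {
  conc <- geometric_series(1e-6, 1.5, 12)
  lc <- log10(conc)
  imax <- 85; mu <- median(lc); s <- 0.4
  ity <- imax * plogis((lc - mu) / s)
  fit <- fit_intensity(conc, ity)
  inv <- invert_intensity(fit, c(6, 17, 34.7, 52.5))
  truth <- 10^(mu + s * qlogis(c(6, 17, 34.7, 52.5) / imax))
  ok <- inv$censor == "none"
  expect_true(any(ok))
  expect_true(all(abs(inv$conc[ok] / truth[ok] - 1) < 0.01))
  # ordered percentages give non-decreasing concentrations
  expect_true(all(diff(inv$conc[!is.na(inv$conc)]) >= 0))
})

test_that("flat intensity ratings yield censored inversions", {
  conc <- geometric_series(1e-6, 1.5, 12)
  fit <- fit_intensity(conc, rep(12, 12))
  expect_true(fit$flat)
  inv <- invert_intensity(fit, c(6, 17))
  expect_true(all(inv$censor == "undefined"))
})

test_that("fold ranges reproduce the published spans", {
  expect_equal(fold_range(c(2.0e-6, 5.0e-5))$fold, 25)   # grosheimin recognition
  expect_equal(fold_range(c(9.9e-6, 5.0e-5))$fold, 5)    # grosheimin strong
  expect_equal(fold_range(c(1.6e-6, 4.0e-5))$fold, 25)   # quinine recognition
  expect_equal(fold_range(c(2.3e-6, 4.0e-5))$fold, 17)   # cascarillin recognition
  expect_equal(fold_range(c(2.6e-8, 1.0e-6))$fold, 38)   # quassin recognition
  expect_equal(fold_range(c(4, 4, 4))$fold, 1)
  expect_error(fold_range(c(1, -2)), "positive")
})

test_that("phenotype table keeps measures ordered and censoring clamped", {
  sc <- default_scenario()
  co <- sample_cohort(sc, 10, seed = 3)
  tr <- simulate_psychophysics(co, seed = 3)
  tr <- tr[tr$compound == "grosheimin", ]
  ph <- phenotype_table(tr)
  wide <- reshape(ph[, c("subject", "repetition", "measure", "conc")],
                  idvar = c("subject", "repetition"),
                  timevar = "measure", direction = "wide")
  w <- wide[, paste0("conc.", c("weak", "moderate", "strong", "very_strong"))]
  ok <- stats::complete.cases(w)
  expect_true(all(apply(w[ok, ], 1, function(r) all(diff(r) >= 0))))
  rng <- range(tr$conc)
  expect_true(all(ph$conc >= rng[1] - 1e-12 & ph$conc <= rng[2] + 1e-12,
                  na.rm = TRUE))
})

test_that("no repetition effect arises under the shared-threshold design", {
  sc <- default_scenario()
  co <- sample_cohort(sc, 24, seed = 19)
  tr <- simulate_psychophysics(co, seed = 19)
  ph <- phenotype_table(tr[tr$compound == "amarogentin", ])
  rec <- ph[ph$measure == "recognition" & !is.na(ph$conc), ]
  wide <- reshape(rec[, c("subject", "repetition", "conc")],
                  idvar = "subject", timevar = "repetition",
                  direction = "wide")
  ok <- stats::complete.cases(wide[, -1])
  p <- stats::t.test(log10(wide$conc.1[ok]), log10(wide$conc.2[ok]),
                     paired = TRUE)$p.value
  expect_gt(p, 0.01)
})
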