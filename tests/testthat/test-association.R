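make_balanced <- function(n = 24, reps = 3, effect = 0, sd_subj = 1,
                          sd_rep = 0.3, seed = 1) {
  set.seed(seed)
  g <- rep(c("A/A", "A/G"), each = n / 2)
  subj <- sprintf("S%02d", seq_len(n))
  mu <- rnorm(n, 0, sd_subj) + ifelse(g == "A/G", effect, 0)
  data.frame(subject = rep(subj, each = reps),
             genotype = rep(g, each = reps),
             y = rep(mu, each = reps) + rnorm(n * reps, 0, sd_rep))
}

test_that("the mixed-model F equals the subject-means ANOVA on balanced data", {
  for (seed in 1:5) {
    d <- make_balanced(seed = seed, effect = 0.4)
    fit <- fit_lmm(d$y, d$genotype, d$subject)
    sm <- tapply(d$y, d$subject, mean)
    sg <- tapply(d$genotype, d$subject, `[`, 1)
    p_oracle <- stats::anova(stats::lm(sm ~ factor(sg)))[["Pr(>F)"]][1]
    expect_equal(fit$p, p_oracle, tolerance = 1e-6)
    expect_equal(fit$method, "lmm")
  }
})

test_that("degenerate inputs are flagged rather than raised", {
  d <- make_balanced()
  d$y <- 0
  fit <- fit_lmm(d$y, d$genotype, d$subject)
  expect_true(fit$degenerate)
  expect_equal(fit$p, 1)
  one <- fit_lmm(rnorm(30), rep("A/A", 30), rep(sprintf("S%d", 1:10), each = 3))
  expect_true(one$degenerate)
})

test_that("Bonferroni decisions follow p <= alpha/m", {
  expect_true(bonferroni(0.04, 1)$reject)
  expect_true(bonferroni(0.004, 10)$reject)
  expect_false(bonferroni(0.006, 10)$reject)
  expect_equal(bonferroni(c(0.01, 0.2), 2)$p_adj, c(0.02, 0.4))
})

test_that("the permutation threshold is ~alpha for one test and LD-duplication invariant", {
  set.seed(41)
  n <- 48
  ph <- data.frame(subject = rep(sprintf("S%02d", 1:n), each = 3),
                   compound = "x", measure = "recognition",
                   conc = 10^rnorm(3 * n, -5, 0.3), censor = "none",
                   outlier = FALSE,
                   repetition = rep(1:3, n))
  g <- setNames(rep(c("A/A", "A/G", "G/G"), c(20, 20, 8)), sprintf("S%02d", 1:n))
  cfg <- scan_config(n_perm = 3000, seed = 9)
  one <- experimentwide_threshold(ph, list(s1 = g), cfg)
  expect_equal(one$alpha_star, 0.05, tolerance = 0.3)
  # perfect mutual LD: duplicated columns change nothing
  dup <- experimentwide_threshold(ph, list(s1 = g, s2 = g, s3 = g), cfg)
  expect_equal(dup$alpha_star, one$alpha_star, tolerance = 1e-12)
})

test_that("class frequency filtering drops rare classes and their subjects", {
  g <- setNames(c(rep("A/A", 30), rep("A/G", 16), rep("G/G", 2)),
                sprintf("S%02d", 1:48))
  cl <- bitterhap:::filter_unit(g, 0.05)
  expect_setequal(unique(cl), c("A/A", "A/G"))
  expect_equal(length(cl), 46)
  expect_null(bitterhap:::filter_unit(setNames(rep("A/A", 48), names(g)), 0.05))
})

test_that("the causal-locus scan localises signals and repulsion masks them", {
  sc <- default_scenario()
  co <- sample_cohort(sc, 48, seed = 31)
  ph <- latent_phenotype(co, seed = 31)
  cfg <- scan_config(n_perm = 1000, seed = 31)
  units <- genotype_units(co, "gene")
  # amarogentin: single causal locus at TAS2R30
  res_am <- scan_associations(ph[ph$compound == "amarogentin", ], units,
                              cfg, level = "gene")
  expect_equal(res_am$unit[which.min(res_am$p)], "TAS2R30")
  blk <- sc$genes$gene[sc$genes$block == "TAS2R31-42"]
  expect_true(any(res_am$significant_experimentwide &
                    res_am$unit %in% blk))
  # absinthin: opposite-phase loci, no experiment-wide signal
  res_ab <- scan_associations(ph[ph$compound == "absinthin", ], units,
                              cfg, level = "gene")
  expect_false(any(res_ab$significant_experimentwide))
  # grosheimin: same-phase loci light up their block
  res_gr <- scan_associations(ph[ph$compound == "grosheimin", ], units,
                              cfg, level = "gene")
  expect_true(any(res_gr$significant_experimentwide & res_gr$unit %in% blk))
})

test_that("scan errors on disjoint subject sets", {
  sc <- two_locus_scenario("coupling")
  co <- sample_cohort(sc, 10, seed = 1)
  ph <- latent_phenotype(co, seed = 1)
  ph$subject <- paste0("X", ph$subject)
  expect_error(scan_associations(ph, genotype_units(co, "snp"),
                                 scan_config()), "no subjects shared")
})

test_that("Sidak threshold has its closed form", {
  expect_equal(sidak_threshold(1), 0.05)
  expect_equal(sidak_threshold(10), 1 - 0.95^(1 / 10))
})
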