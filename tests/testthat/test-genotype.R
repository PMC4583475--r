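test_that("copy number follows the multiplex-PCR decision table", {
  expect_equal(call_copy_number(FALSE, TRUE), 0L)
  expect_equal(call_copy_number(TRUE, FALSE), 2L)
  expect_equal(call_copy_number(TRUE, TRUE), 1L)
  expect_equal(call_copy_number(c(TRUE, FALSE), c(TRUE, TRUE)), c(1L, 0L))
  expect_error(call_copy_number(FALSE, FALSE), "no-call")
})

test_that("exact HWE test matches enumeration and handles extremes", {
  expect_equal(test_hwe(25, 50, 25), 1)
  expect_lt(test_hwe(50, 0, 50), 1e-6)
  expect_equal(test_hwe(3, 5, 2), oracle_hwe(3, 5, 2), tolerance = 1e-12)
  for (cnt in list(c(10, 2, 8), c(1, 1, 1), c(0, 5, 0), c(12, 30, 40))) {
    expect_equal(test_hwe(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  expect_error(test_hwe(-1, 2, 3), "non-negative")
})

test_that("simulated genotypes reject HWE at close to the nominal rate", {
  # conservative exact test: rate at or slightly below 5%
  set.seed(31)
  n <- 500
  rej <- replicate(1000, {
    p <- runif(1, 0.1, 0.5)
    g <- rmultinom(1, n, c(p^2, 2 * p * (1 - p), (1 - p)^2))
    test_hwe(g[1], g[2], g[3]) <= 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.07)
})

test_that("phasing is exact for unambiguous subjects", {
  g <- matrix(c("A/A", "C/C", "A/A", "C/C", "G/G", "C/C"), 3, 2, byrow = TRUE)
  r <- phase_em(g, seed = 1)
  expect_true(all(r$phase$posterior == 1))
  expect_equal(r$phase$hap1, c("A|C", "A|C", "G|C"))
  # a single heterozygous site is phase-unambiguous
  g2 <- matrix(c("A/G", "C/C"), 1, 2)
  r2 <- phase_em(g2, seed = 1)
  expect_equal(sort(c(r2$phase$hap1, r2$phase$hap2)), c("A|C", "G|C"))
  expect_equal(r2$phase$posterior, 1)
})

test_that("EM frequencies match the grid-search likelihood oracle on a coupling design", {
  # double heterozygotes plus unambiguous subjects establishing
  # coupling-phase excess
  rows <- c(rep("A/A|C/C", 6), rep("G/G|T/T", 4), rep("A/G|C/T", 8),
            "A/A|C/T", "A/G|T/T")
  g <- do.call(rbind, lapply(strsplit(rows, "|", fixed = TRUE), identity))
  r <- phase_em(g, seed = 1, n_restarts = 5)
  orc <- oracle_em_2site(rows, step = 0.02)
  # the EM must reach at least the grid-search maximum, with matching argmax
  expect_gte(r$loglik, orc$loglik - 1e-6)
  f_em <- setNames(r$haplotypes$frequency, r$haplotypes$haplotype)
  for (h in names(orc$freq)[orc$freq > 0]) {
    key <- paste(strsplit(h, "")[[1]], collapse = "|")
    expect_lt(abs(unname(f_em[key]) - unname(orc$freq[h])), 0.03)
  }
  # coupling diplotype assigned to the double heterozygotes
  dh <- which(rows == "A/G|C/T")
  expect_true(all(r$phase$hap1[dh] == "A|C" | r$phase$hap1[dh] == "G|T"))
  f <- setNames(r$haplotypes$frequency, r$haplotypes$haplotype)
  expect_gt(f[["A|C"]] + f[["G|T"]], 0.8)
})

test_that("EM log-likelihood is non-decreasing and frequencies sum to one", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 30
    hap_pool <- c("A|C|T", "G|C|T", "A|T|T", "G|T|A")
    f <- c(0.4, 0.3, 0.2, 0.1)
    h1 <- sample(hap_pool, n, TRUE, f); h2 <- sample(hap_pool, n, TRUE, f)
    g <- t(mapply(unphase_pair, h1, h2))
    r <- phase_em(g, seed = rep)
    expect_true(all(diff(r$loglik_path) > -1e-8))
    expect_equal(sum(r$haplotypes$frequency), 1, tolerance = 1e-9)
    # round trip: unphasing the reported pairs reproduces the genotypes
    for (i in seq_len(n)) {
      expect_equal(unphase_pair(r$phase$hap1[i], r$phase$hap2[i]),
                   unname(g[i, ]))
    }
  }
})

test_that("hemizygous and zero-copy subjects phase with the deletion state", {
  g <- rbind(c("A/A", "C/C"), c("A", "C"), c(NA, NA))
  r <- phase_em(g, copies = c(2L, 1L, 0L), seed = 1)
  expect_equal(sort(c(r$phase$hap1[2], r$phase$hap2[2])), c("A|C", "DEL"))
  expect_equal(c(r$phase$hap1[3], r$phase$hap2[3]), c("DEL", "DEL"))
})

test_that("haplotype naming ranks by frequency with documented tie-breaks", {
  hs <- data.frame(haplotype = c("G|T", "A|C"), frequency = c(0.4, 0.6))
  expect_equal(name_haplotypes(hs)$name[1], "H1")
  expect_equal(name_haplotypes(hs)$haplotype[1], "A|C")
  tie <- data.frame(haplotype = c("G|G", "A|A"), frequency = c(0.5, 0.5))
  expect_equal(name_haplotypes(tie)$haplotype, c("A|A", "G|G"))
  # deletion named separately; long-range prefix supported
  del <- data.frame(haplotype = c("A", "DEL"), frequency = c(0.5, 0.5))
  expect_equal(name_haplotypes(del)$name, c("H1", "DEL"))
  fig5 <- data.frame(haplotype = c("d", "c", "b", "a"),
                     frequency = c(0.16, 0.20, 0.22, 0.30))
  nm <- name_haplotypes(fig5, prefix = "H-LR")
  expect_equal(nm$name, paste0("H-LR", 1:4))
  expect_equal(nm$frequency, c(0.30, 0.22, 0.20, 0.16))
})

test_that("subjects with missing genotypes are excluded and reported unphased", {
  g <- rbind(c("A/G", "C/T"), c(NA, "C/C"))
  r <- phase_em(g, seed = 1)
  expect_true(is.na(r$phase$hap1[2]))
  expect_false(is.na(r$phase$hap1[1]))
})

test_that("EM phasing switch error stays below 5% on a realistic cohort", {
  # n = 200 subjects, 4 biallelic sites, all pool haplotypes common
  set.seed(17)
  pool <- c("A|C|G|T", "G|C|G|T", "A|T|G|A", "G|T|A|T", "A|C|A|A")
  f <- c(0.35, 0.25, 0.2, 0.12, 0.08)
  n <- 200
  h1 <- sample(pool, n, TRUE, f); h2 <- sample(pool, n, TRUE, f)
  g <- t(mapply(unphase_pair, h1, h2))
  r <- phase_em(g, seed = 3)
  err <- switch_error_rate(h1, h2, r$phase$hap1, r$phase$hap2)
  expect_lt(err, 0.05)
})
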