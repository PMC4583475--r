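units_df <- function(n, chrom = "chr1") {
  data.frame(unit = paste0("u", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * 1000)
}

test_that("three observed gametes keep two sites in one block", {
  hm <- cbind(u1 = c(rep("A", 40), rep("G", 60)),
              u2 = c(rep("C", 40), rep("T", 30), rep("C", 30)))
  part <- four_gamete_blocks(hm, units_df(2))
  expect_equal(length(unique(part$block)), 1)
})

test_that("a single four-gamete pair splits the run exactly there", {
  # sites 1-2 and 3-4 perfectly coupled; recombination evidence only
  # between the pairs
  set.seed(5)
  h12 <- sample(rep(c("A", "G"), each = 50))
  h34 <- sample(rep(c("C", "T"), each = 50))
  hm <- cbind(u1 = h12, u2 = h12, u3 = h34, u4 = h34)
  part <- four_gamete_blocks(hm, units_df(4))
  expect_equal(part$block[1], part$block[2])
  expect_equal(part$block[3], part$block[4])
  expect_false(part$block[2] == part$block[3])
})

test_that("the partition is valid and minimal against the enumeration oracle", {
  set.seed(61)
  for (rep in 1:20) {
    m <- sample(3:6, 1)
    n <- 120
    # generate sites with varying dependence to mix evidence patterns
    base <- sample(0:1, n, TRUE)
    hm <- vapply(seq_len(m), function(j) {
      x <- if (runif(1) < 0.5) base else sample(0:1, n, TRUE)
      flip <- runif(n) < runif(1, 0, 0.3)
      ifelse(xor(x == 1, flip), "G", "A")
    }, character(n))
    colnames(hm) <- paste0("u", 1:m)
    ud <- units_df(m)
    keep <- vapply(1:m, function(j) min(table(hm[, j])) / n >= 0.05, TRUE)
    if (sum(keep) < 2) next
    part <- four_gamete_blocks(hm, ud)
    kept <- part$unit
    bin <- vapply(kept, function(u) as.integer(hm[, u] == "A"),
                  integer(n))
    orc <- oracle_min_blocks(bin)
    # validity: no within-block pair shows four-gamete evidence
    for (b in unique(part$block)) {
      mem <- match(part$unit[part$block == b], kept)
      if (length(mem) > 1) {
        combs <- utils::combn(mem, 2)
        for (k in seq_len(ncol(combs))) {
          expect_false(orc$evidence[combs[1, k], combs[2, k]])
        }
      }
    }
    # minimality: the greedy maximal-run count equals the DP minimum
    expect_equal(length(unique(part$block)), orc$min_blocks)
  }
})

test_that("the default scenario yields the six published gene blocks", {
  sc <- default_scenario()
  co <- sample_cohort(sc, 48, seed = 1)
  hm <- true_haplotype_matrix(co, "gene")
  units <- data.frame(unit = sc$genes$gene, chrom = sc$genes$chrom,
                      pos = sc$genes$pos)
  part <- four_gamete_blocks(hm, units)
  bs <- block_summary(part)
  multi <- bs$members[bs$n_units > 1]
  expect_equal(multi, c(
    "TAS2R3,TAS2R4,TAS2R5",
    "TAS2R40,TAS2R60",
    "TAS2R42,TAS2R30,TAS2R45,TAS2R43,TAS2R46,TAS2R31",
    "TAS2R19,TAS2R20,TAS2R50",
    "TAS2R14,TAS2R13",
    "TAS2R9,TAS2R8,TAS2R7"))
  # monomorphic genes (no coding SNPs) are excluded from the partition
  expect_true(all(c("TAS2R39", "TAS2R10") %in% attr(part, "excluded")))
  # reversal symmetry holds on this clean partition
  rev_units <- units[rev(seq_len(nrow(units))), ]
  part_rev <- four_gamete_blocks(hm, rev_units[order(rev_units$chrom,
                                                     rev_units$pos), ])
  expect_equal(length(unique(part_rev$block)), length(unique(part$block)))
})

test_that("raising the cutoff never increases the number of blocks", {
  set.seed(77)
  for (rep in 1:10) {
    m <- 6; n <- 150
    hm <- vapply(1:m, function(j) {
      p <- runif(1, 0.3, 0.7)
      sample(c("A", "G"), n, TRUE, c(p, 1 - p))
    }, character(n))
    colnames(hm) <- paste0("u", 1:m)
    ud <- units_df(m)
    n_blocks <- vapply(c(0.05, 0.1, 0.2), function(cut) {
      p <- four_gamete_blocks(hm, ud, cutoff = cut, min_freq = 0.05)
      length(unique(p$block))
    }, numeric(1))
    expect_true(all(diff(n_blocks) <= 0))
  }
})

test_that("manual overrides win over the algorithm and keep contiguity", {
  set.seed(6)
  h12 <- sample(rep(c("A", "G"), each = 50))
  h34 <- sample(rep(c("C", "T"), each = 50))
  hm <- cbind(u1 = h12, u2 = h12, u3 = h34, u4 = h34)
  part <- four_gamete_blocks(hm, units_df(4),
                             overrides = c(u3 = "left", u2 = "left"))
  # u2 and u3 share a forced label -> merged into one contiguous block
  blocks <- split(part$unit, part$block)
  expect_true(any(vapply(blocks, function(b)
    all(c("u2", "u3") %in% b), logical(1))))
})

test_that("unsorted unit positions are rejected", {
  hm <- cbind(u1 = rep(c("A", "G"), 10), u2 = rep(c("C", "T"), 10))
  bad <- data.frame(unit = c("u1", "u2"), chrom = "chr1", pos = c(200, 100))
  expect_error(four_gamete_blocks(hm, bad), "ordered")
})
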