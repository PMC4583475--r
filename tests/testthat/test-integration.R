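# receptor-function fits shaped like dose_response_table output, built
# from the scenario's published parameters
fits_from_table <- function(sc, compound) {
  rt <- sc$receptor_table[sc$receptor_table$compound == compound &
                            sc$receptor_table$allele != "DEL", ]
  data.frame(gene = rt$gene, allele = rt$allele,
             construct = paste(rt$gene, rt$allele, sep = "-"),
             compound = compound, threshold_conc = rt$activation_threshold,
             ec50 = rt$ec50, amplitude = rt$amplitude,
             activated = rt$amplitude > 0, stringsAsFactors = FALSE)
}

test_that("alleles classify by sensitivity and phenotype relevance", {
  sc <- default_scenario()
  fits <- fits_from_table(sc, "amarogentin")
  rft <- classify_alleles(fits, subject_range = c(1.2e-8, 2.0e-7))
  get <- function(g, a, col) rft[rft$gene == g & rft$allele == a, col]
  # TAS2R30-H1 activates within the subjects' range -> explanatory
  expect_true(get("TAS2R30", "H1", "explanatory"))
  expect_equal(get("TAS2R30", "H1", "class"), "sensitive")
  # TAS2R46-H1 activates at 3e-5, far above the range -> not explanatory
  expect_false(get("TAS2R46", "H1", "explanatory"))
  # the truncated TAS2R46-H2 never activates
  expect_equal(get("TAS2R46", "H2", "class"), "nonfunctional")
})

test_that("missing fits for common alleles are reported as gaps", {
  sc <- default_scenario()
  fits <- fits_from_table(sc, "grosheimin")
  expect_warning(
    rft <- classify_alleles(fits, common_alleles = data.frame(
      gene = c("TAS2R43", "TAS2R31"), allele = c("H1", "H1"))),
    "TAS2R31")
  expect_equal(attr(rft, "gaps")$gene, "TAS2R31")
})

test_that("pure four-haplotype repulsion cohorts carry exactly two sensitive copies", {
  sc <- default_scenario()
  # pool restricted to the four common long-range haplotypes
  f <- sc$lrh_pool[["TAS2R31-42"]]$freq
  sc$lrh_pool[["TAS2R31-42"]]$freq <- f / sum(f)
  co <- sample_cohort(sc, 200, seed = 13)
  fits <- fits_from_table(sc, "absinthin")
  rft <- classify_alleles(fits, subject_range = c(5.2e-8, 2.0e-6))
  ps <- phase_summary(co, rft, "absinthin")
  expect_equal(ps$phase_mode, "repulsion")
  expect_setequal(ps$genes, c("TAS2R30", "TAS2R46"))
  expect_true(all(ps$dosage == 2))
  expect_equal(ps$fractions, c(0, 0, 1))
  expect_equal(sum(ps$fractions), 1)
})

test_that("co-resident sensitive alleles read as coupling; one locus as single_locus", {
  sc <- default_scenario()
  co <- sample_cohort(sc, 100, seed = 14)
  fits <- fits_from_table(sc, "grosheimin")
  rft <- classify_alleles(fits, subject_range = c(2.0e-6, 5.0e-5))
  ps <- phase_summary(co, rft, "grosheimin")
  expect_equal(ps$phase_mode, "coupling")
  expect_true(all(ps$dosage %in% 0:2))
  # amarogentin's sensitive allele set reduces to TAS2R30 alone
  fits_am <- fits_from_table(sc, "amarogentin")
  fits_am <- fits_am[fits_am$gene == "TAS2R30", ]
  rft_am <- classify_alleles(fits_am, subject_range = c(1.2e-8, 2.0e-7))
  ps_am <- phase_summary(co, rft_am, "amarogentin")
  expect_equal(ps_am$phase_mode, "single_locus")
})

test_that("phase summaries are pure functions of their inputs", {
  sc <- default_scenario()
  co <- sample_cohort(sc, 60, seed = 15)
  rft <- classify_alleles(fits_from_table(sc, "grosheimin"),
                          subject_range = c(2.0e-6, 5.0e-5))
  a <- phase_summary(co, rft, "grosheimin")
  b <- phase_summary(co, rft, "grosheimin")
  expect_identical(a, b)
})

test_that("the candidate filter separates causal, passenger and phase-masked loci", {
  sc <- default_scenario()
  gene_blocks <- sc$genes[, c("gene", "block")]
  # amarogentin: significant block + inventory + explanatory only at TAS2R30
  assoc <- data.frame(unit = c("TAS2R30", "TAS2R31"),
                      compound = "amarogentin",
                      significant_experimentwide = TRUE)
  rft <- classify_alleles(fits_from_table(sc, "amarogentin"),
                          subject_range = c(1.2e-8, 2.0e-7))
  rep_am <- candidate_filter(assoc, rft, sc$inventory, gene_blocks)
  cls <- setNames(rep_am$classification, rep_am$gene)
  expect_equal(unname(cls["TAS2R30"]), "causal")
  expect_equal(unname(cls["TAS2R43"]), "linked_passenger")
  expect_equal(unname(cls["TAS2R46"]), "linked_passenger")

  # absinthin: no significant units; repulsion phase -> masked
  co <- sample_cohort(sc, 100, seed = 16)
  rft_ab <- classify_alleles(fits_from_table(sc, "absinthin"),
                             subject_range = c(5.2e-8, 2.0e-6))
  ps <- phase_summary(co, rft_ab, "absinthin")
  none <- data.frame(unit = character(0), compound = character(0),
                     significant_experimentwide = logical(0))
  rep_ab <- candidate_filter(none, rft_ab, sc$inventory, gene_blocks,
                             phase_modes = list(absinthin = ps))
  cls_ab <- setNames(rep_ab$classification, rep_ab$gene)
  expect_equal(unname(cls_ab["TAS2R30"]), "phase_masked")
  expect_equal(unname(cls_ab["TAS2R46"]), "phase_masked")

  # an empty inventory leaves everything unexplained
  rep_em <- candidate_filter(none, rft_ab, list(), gene_blocks)
  expect_true(all(rep_em$classification == "unexplained"))
})
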