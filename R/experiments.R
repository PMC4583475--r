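#' Latent-model phenotype table
#'
#' Generates a phenotype table directly from the latent sensitivity model
#' (subject latent log10 threshold plus small repetition noise), bypassing
#' trial simulation and psychometric fitting. Useful for simulation studies
#' of the association machinery where the psychometric stage's noise is not
#' under study.
#'
#' @param cohort a `tas2r_cohort`.
#' @param seed integer seed.
#' @param n_reps repetitions per subject.
#' @param rep_sd repetition noise, log10 units.
#' @param measure measure label for the rows.
#' @return data.frame shaped like [phenotype_table()] output.
#' @export
latent_phenotype <- function(cohort, seed = cohort$scenario$seed,
                             n_reps = 3L, rep_sd = 0.05,
                             measure = "recognition") {
  lat <- latent_sensitivity(cohort, seed = child_seed(seed, "latent"))
  idx <- rep(seq_len(nrow(lat)), each = n_reps)
  noise <- with_local_seed(child_seed(seed, "reps"),
                           stats::rnorm(length(idx), 0, rep_sd))
  data.frame(subject = lat$subject[idx], compound = lat$compound[idx],
             repetition = rep(seq_len(n_reps), nrow(lat)),
             measure = measure, conc = 10^(lat$latent_log10[idx] + noise),
             censor = "none", outlier = FALSE, stringsAsFactors = FALSE)
}

#' Paired coupling-vs-repulsion association experiment
#'
#' Simulates pairs of two-locus cohorts with identical allele effect sizes
#' whose sensitive alleles sit either in coupling or in repulsion phase
#' ([two_locus_scenario()]), runs the SNP-level association scan with the
#' permutation experiment-wide threshold on each, and records whether any
#' unit reached experiment-wide significance. In coupling phase the
#' insensitive-haplotype homozygotes form a distinct phenotype class and
#' the scan should fire; in repulsion phase every subject carries a
#' sensitive allele and the scan should stay silent — the study's central
#' association/no-association contrast as a testable property.
#'
#' @param n_pairs number of paired replicates.
#' @param n_subjects cohort size per replicate.
#' @param seed integer seed.
#' @param n_perm permutations per threshold.
#' @param effect log10 separation of the two allele classes (via the
#'   sensitive/insensitive activation thresholds).
#' @param subject_sd subject noise, log10 units.
#' @return data.frame (pair, coupling_hit, repulsion_hit, contrast); the
#'   contrast is TRUE when the coupling scan fired and the repulsion scan
#'   did not.
#' @export
phase_contrast_experiment <- function(n_pairs = 50L, n_subjects = 48L,
                                      seed = 1L, n_perm = 1000L,
                                      effect = 1, subject_sd = 0.25) {
  sc_c <- two_locus_scenario("coupling", thr_sensitive = 1e-6,
                             thr_insensitive = 10^(log10(1e-6) + effect),
                             subject_sd = subject_sd,
                             n_subjects = n_subjects)
  sc_r <- two_locus_scenario("repulsion", thr_sensitive = 1e-6,
                             thr_insensitive = 10^(log10(1e-6) + effect),
                             subject_sd = subject_sd,
                             n_subjects = n_subjects)
  one <- function(scn, s) {
    co <- sample_cohort(scn, n_subjects, seed = s)
    ph <- latent_phenotype(co, seed = child_seed(s, "pheno"))
    units <- genotype_units(co, "snp")
    cfg <- scan_config(n_perm = n_perm, seed = child_seed(s, "perm"))
    res <- scan_associations(ph, units, cfg, level = "snp",
                             experimentwide = TRUE)
    any(res$significant_experimentwide)
  }
  out <- data.frame(pair = seq_len(n_pairs), coupling_hit = NA,
                    repulsion_hit = NA)
  for (i in seq_len(n_pairs)) {
    out$coupling_hit[i] <- one(sc_c, child_seed(seed, paste0("c", i)))
    out$repulsion_hit[i] <- one(sc_r, child_seed(seed, paste0("r", i)))
  }
  out$contrast <- out$coupling_hit & !out$repulsion_hit
  out
}
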