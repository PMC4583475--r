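#' Construct a simulation scenario
#'
#' A scenario bundles everything the synthetic-cohort generator needs: the
#' gene/site map organised in haplotype blocks, the long-range haplotype
#' (LRH) pool per block, the receptor pharmacology table, the link between
#' receptor activation thresholds and subject-level perceptual thresholds,
#' and the psychophysics and plate designs.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `block`, `pos`,
#'   `cnv` (logical; whole-gene deletion alleles allowed).
#' @param sites data.frame with columns `site_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `consequence`.
#' @param gene_haps named list: gene -> named list of haplotype allele
#'   vectors over that gene's sites (site order). The whole-gene deletion
#'   state is not listed here; it is the reserved label `"DEL"`.
#' @param lrh_pool named list: block -> `list(freq = , comp = )` where
#'   `freq` is a named numeric vector of LRH frequencies (sum <= 1; the
#'   remainder is drawn as rare, singly mutated haplotypes) and `comp` a
#'   named list mapping each LRH to a named character vector gene -> gene
#'   haplotype name (or `"DEL"`).
#' @param receptor_table data.frame with columns `compound`, `gene`,
#'   `allele`, `activation_threshold` (M; NA if never activated), `ec50`
#'   (M), `amplitude` (peak delta-F/F; 0 for nonfunctional), `hill_n`.
#' @param link data.frame with columns `compound`, `offset`, `slope`,
#'   `subject_sd`: subject latent log10 recognition threshold =
#'   offset + slope * log10(best carried activation threshold) + N(0, sd).
#' @param psych_design data.frame, one row per compound, with the 4-AFC
#'   concentration series (`start`, `ratio`, `n_steps`, `n_reps`, `guess`)
#'   and response-curve parameters (see [default_scenario()]).
#' @param plate_design list describing the in-vitro plate layout (see
#'   [default_scenario()]).
#' @param inventory named list compound -> character vector of genes with
#'   known baseline responsiveness (editable receptor-agonist inventory).
#' @param n_subjects default cohort size.
#' @param seed default seed.
#' @return An object of class `tas2r_scenario`.
#' @export
scenario <- function(genes, sites, gene_haps, lrh_pool, receptor_table,
                     link, psych_design, plate_design, inventory = list(),
                     n_subjects = 48L, seed = 1L) {
  s <- structure(
    list(genes = genes, sites = sites, gene_haps = gene_haps,
         lrh_pool = lrh_pool, receptor_table = receptor_table, link = link,
         psych_design = psych_design, plate_design = plate_design,
         inventory = inventory, n_subjects = as.integer(n_subjects),
         seed = as.integer(seed)),
    class = "tas2r_scenario")
  validate_scenario(s)
  s
}

#' Validate a scenario's invariants
#'
#' Checks frequency bounds (all LRH frequencies in \[0,1\], per-block sums
#' <= 1), ascending geometric series (ratio > 1, concentrations > 0),
#' non-negative receptor amplitudes, and consistency of LRH compositions
#' with the declared gene haplotypes.
#'
#' @param s a `tas2r_scenario`.
#' @return `s`, invisibly; errors on violation.
#' @export
validate_scenario <- function(s) {
  stopifnot(inherits(s, "tas2r_scenario"))
  for (b in names(s$lrh_pool)) {
    f <- s$lrh_pool[[b]]$freq
    if (any(f < 0) || any(f > 1)) {
      stop(sprintf("block %s: LRH frequencies must lie in [0,1]", b), call. = FALSE)
    }
    if (sum(f) > 1 + 1e-9) {
      stop(sprintf("block %s: LRH frequencies sum to %.3f > 1", b, sum(f)), call. = FALSE)
    }
    bg <- s$genes$gene[s$genes$block == b]
    for (h in names(s$lrh_pool[[b]]$comp)) {
      comp <- s$lrh_pool[[b]]$comp[[h]]
      if (!setequal(names(comp), bg)) {
        stop(sprintf("block %s LRH %s: composition genes do not match block genes", b, h),
             call. = FALSE)
      }
      for (g in names(comp)) {
        if (comp[[g]] != "DEL" && !comp[[g]] %in% names(s$gene_haps[[g]])) {
          stop(sprintf("block %s LRH %s: unknown haplotype %s at %s", b, h, comp[[g]], g),
               call. = FALSE)
        }
        if (comp[[g]] == "DEL" && !s$genes$cnv[s$genes$gene == g]) {
          stop(sprintf("gene %s is not CNV-capable but carries DEL", g), call. = FALSE)
        }
      }
    }
  }
  pd <- s$psych_design
  stop_if_not_positive(pd$start, "psych_design$start")
  if (any(pd$ratio <= 1)) stop("psych_design$ratio must be > 1", call. = FALSE)
  if (any(s$receptor_table$amplitude < 0)) {
    stop("receptor amplitudes must be >= 0", call. = FALSE)
  }
  thr <- s$receptor_table$activation_threshold
  if (any(!is.na(thr) & thr <= 0)) stop("activation thresholds must be > 0", call. = FALSE)
  if (any(s$plate_design$conc <= 0)) stop("plate concentrations must be > 0", call. = FALSE)
  invisible(s)
}

# Choose per-allele Hill coefficients so the dose-response curve first
# exceeds the assay's resolvable response (delta) at the published
# activation threshold: n solves amp / (1 + (ec50/thr)^n) = delta.
calibrate_hill_n <- function(rt, delta = 0.005, lo = 0.8, hi = 4) {
  ok <- !is.na(rt$activation_threshold) & rt$amplitude > delta &
    !is.na(rt$ec50)
  n <- rt$hill_n
  ratio <- rt$ec50[ok] / rt$activation_threshold[ok]
  n[ok] <- ifelse(ratio > 1,
                  log(rt$amplitude[ok] / delta - 1) / log(ratio),
                  hi)
  rt$hill_n <- pmin(hi, pmax(lo, n))
  rt
}

# binary-encoded haplotype allele vectors: H1 all-ref, H2 alt at site 1,
# H3 alt at site 2, H4 alt at sites 1+2
hap_vectors <- function(n_haps, ref, alt) {
  n_sites <- length(ref)
  v <- list()
  pat <- list(integer(0), 1L, 2L, c(1L, 2L))
  for (i in seq_len(n_haps)) {
    a <- ref
    idx <- pat[[i]]
    idx <- idx[idx <= n_sites]
    a[idx] <- alt[idx]
    v[[paste0("H", i)]] <- a
  }
  v
}

#' Default synthetic scenario
#'
#' Encodes the study design the package emulates: 48 diploid subjects; the
#' 25-gene TAS2R family on chromosomes 5, 7 and 12 with six multi-gene
#' haplotype blocks (TAS2R3-5, TAS2R39-60, TAS2R7-10, TAS2R13-14,
#' TAS2R50-19, TAS2R31-42); long-range haplotypes for the TAS2R31-42 block
#' at frequencies 0.30/0.22/0.20/0.16 carrying the published combinations
#' of TAS2R30/-43/-46 alleles (including the TAS2R43 whole-gene deletion and
#' the truncated TAS2R46-H2); receptor dose-response parameters taken from
#' the published per-allele thresholds, EC50s and amplitudes; 12-step
#' 1.5-ratio concentration series in triplicate per compound; and 6-replicate
#' half-log dose-response plates with day effects.
#'
#' @param n_subjects cohort size (default 48).
#' @param seed default seed.
#' @return A `tas2r_scenario`.
#' @export
default_scenario <- function(n_subjects = 48L, seed = 1L) {
  # block layout: list(block, chrom, base position, genes = c(name = n_haps))
  # cnv genes flagged separately; gene order is chromosomal order
  layout <- list(
    list(block = "TAS2R1",     chrom = "chr5",  base = 9.6e6,    genes = c(TAS2R1 = 2)),
    list(block = "TAS2R16",    chrom = "chr7",  base = 122.6e6,  genes = c(TAS2R16 = 2)),
    list(block = "TAS2R3-5",   chrom = "chr7",  base = 141.0e6,  genes = c(TAS2R3 = 2, TAS2R4 = 2, TAS2R5 = 2)),
    list(block = "TAS2R38",    chrom = "chr7",  base = 141.4e6,  genes = c(TAS2R38 = 2)),
    list(block = "TAS2R39-60", chrom = "chr7",  base = 141.7e6,  genes = c(TAS2R39 = 1, TAS2R40 = 2, TAS2R60 = 2)),
    list(block = "TAS2R41",    chrom = "chr7",  base = 142.0e6,  genes = c(TAS2R41 = 2)),
    list(block = "TAS2R31-42", chrom = "chr12", base = 11.05e6,
         genes = c(TAS2R42 = 2, TAS2R30 = 2, TAS2R45 = 2, TAS2R43 = 2, TAS2R46 = 3, TAS2R31 = 4)),
    list(block = "TAS2R50-19", chrom = "chr12", base = 11.25e6,
         genes = c(TAS2R19 = 3, TAS2R20 = 4, TAS2R50 = 4)),
    list(block = "TAS2R13-14", chrom = "chr12", base = 11.35e6, genes = c(TAS2R14 = 3, TAS2R13 = 2)),
    list(block = "TAS2R7-10",  chrom = "chr12", base = 11.42e6,
         genes = c(TAS2R10 = 1, TAS2R9 = 3, TAS2R8 = 2, TAS2R7 = 2))
  )
  cnv_genes <- c("TAS2R43", "TAS2R45")
  base_pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))

  genes <- NULL; sites <- NULL; gene_haps <- list()
  site_k <- 0L
  for (bl in layout) {
    gpos <- bl$base + (seq_along(bl$genes) - 1L) * 28000
    for (i in seq_along(bl$genes)) {
      g <- names(bl$genes)[i]; nh <- bl$genes[[i]]
      n_sites <- c(0L, 1L, 2L, 2L)[nh]
      genes <- rbind(genes, data.frame(
        gene = g, chrom = bl$chrom, block = bl$block, pos = gpos[i],
        cnv = g %in% cnv_genes, stringsAsFactors = FALSE))
      if (n_sites > 0) {
        bp <- base_pairs[[(site_k %% 4L) + 1L]]
        ref <- rep(bp[1], n_sites); alt <- rep(bp[2], n_sites)
        csq <- rep("missense", n_sites)
        if (g == "TAS2R46") csq[1] <- "nonsense"   # premature stop on H2
        if (g %in% c("TAS2R42", "TAS2R9")) csq[1] <- "synonymous"
        if (g %in% c("TAS2R31", "TAS2R20")) csq[n_sites] <- "synonymous"
        sid <- sprintf("%s_s%d", g, seq_len(n_sites))
        sites <- rbind(sites, data.frame(
          site_id = sid, gene = g, chrom = bl$chrom,
          pos = gpos[i] + 150 + (seq_len(n_sites) - 1L) * 300,
          ref = ref, alt = alt, consequence = csq, stringsAsFactors = FALSE))
        gene_haps[[g]] <- hap_vectors(nh, ref, alt)
        site_k <- site_k + 1L
      } else {
        gene_haps[[g]] <- list(H1 = character(0))
      }
    }
  }

  lrh <- function(freqs, comp_rows) {
    comp <- lapply(comp_rows, function(r) r)
    names(comp) <- paste0("LRH", seq_along(comp_rows))
    list(freq = stats::setNames(freqs, names(comp)), comp = comp)
  }
  # within-block compositions are chosen mutation-compatible: for every
  # within-block gene pair, one of the four major-vs-rest gamete classes is
  # absent from the pool, so four-gamete recombination evidence arises only
  # between blocks (and from rare sampling noise)
  lrh_pool <- list(
    "TAS2R1"  = lrh(c(0.68, 0.30), list(c(TAS2R1 = "H1"), c(TAS2R1 = "H2"))),
    "TAS2R16" = lrh(c(0.72, 0.26), list(c(TAS2R16 = "H1"), c(TAS2R16 = "H2"))),
    "TAS2R3-5" = lrh(c(0.62, 0.33), list(
      c(TAS2R3 = "H1", TAS2R4 = "H1", TAS2R5 = "H1"),
      c(TAS2R3 = "H2", TAS2R4 = "H2", TAS2R5 = "H2"))),
    "TAS2R38" = lrh(c(0.58, 0.40), list(c(TAS2R38 = "H1"), c(TAS2R38 = "H2"))),
    "TAS2R39-60" = lrh(c(0.60, 0.37), list(
      c(TAS2R39 = "H1", TAS2R40 = "H1", TAS2R60 = "H1"),
      c(TAS2R39 = "H1", TAS2R40 = "H2", TAS2R60 = "H2"))),
    "TAS2R41" = lrh(c(0.62, 0.36), list(c(TAS2R41 = "H1"), c(TAS2R41 = "H2"))),
    "TAS2R31-42" = lrh(c(0.30, 0.22, 0.20, 0.16), list(
      c(TAS2R42 = "H2", TAS2R30 = "H1", TAS2R45 = "H1", TAS2R43 = "DEL", TAS2R46 = "H2", TAS2R31 = "H1"),
      c(TAS2R42 = "H1", TAS2R30 = "H2", TAS2R45 = "H1", TAS2R43 = "H1",  TAS2R46 = "H1", TAS2R31 = "H2"),
      c(TAS2R42 = "H1", TAS2R30 = "H1", TAS2R45 = "DEL", TAS2R43 = "DEL", TAS2R46 = "H3", TAS2R31 = "H3"),
      c(TAS2R42 = "H1", TAS2R30 = "H2", TAS2R45 = "H1", TAS2R43 = "H2",  TAS2R46 = "H1", TAS2R31 = "H4"))),
    "TAS2R50-19" = lrh(c(0.32, 0.27, 0.17, 0.12, 0.09), list(
      c(TAS2R19 = "H1", TAS2R20 = "H1", TAS2R50 = "H1"),
      c(TAS2R19 = "H1", TAS2R20 = "H1", TAS2R50 = "H2"),
      c(TAS2R19 = "H1", TAS2R20 = "H2", TAS2R50 = "H4"),
      c(TAS2R19 = "H2", TAS2R20 = "H3", TAS2R50 = "H3"),
      c(TAS2R19 = "H3", TAS2R20 = "H4", TAS2R50 = "H3"))),
    "TAS2R13-14" = lrh(c(0.50, 0.32, 0.15), list(
      c(TAS2R14 = "H1", TAS2R13 = "H1"),
      c(TAS2R14 = "H2", TAS2R13 = "H2"),
      c(TAS2R14 = "H3", TAS2R13 = "H1"))),
    "TAS2R7-10" = lrh(c(0.38, 0.28, 0.22, 0.09), list(
      c(TAS2R10 = "H1", TAS2R9 = "H1", TAS2R8 = "H1", TAS2R7 = "H1"),
      c(TAS2R10 = "H1", TAS2R9 = "H2", TAS2R8 = "H2", TAS2R7 = "H1"),
      c(TAS2R10 = "H1", TAS2R9 = "H1", TAS2R8 = "H1", TAS2R7 = "H2"),
      c(TAS2R10 = "H1", TAS2R9 = "H3", TAS2R8 = "H2", TAS2R7 = "H1")))
  )

  rt <- function(compound, gene, allele, thr, ec50, amp, n = 1) {
    data.frame(compound = compound, gene = gene, allele = allele,
               activation_threshold = thr, ec50 = ec50, amplitude = amp,
               hill_n = n, stringsAsFactors = FALSE)
  }
  receptor_table <- rbind(
    rt("amarogentin", "TAS2R30", "H1", 1.0e-8, 4.1e-7, 0.50),
    rt("amarogentin", "TAS2R30", "H2", 3.0e-7, 3.9e-7, 0.12),
    rt("amarogentin", "TAS2R43", "H1", 3.0e-4, 5.0e-4, 0.15),
    rt("amarogentin", "TAS2R43", "H2", 3.0e-4, 5.0e-4, 0.15),
    rt("amarogentin", "TAS2R43", "DEL", NA, NA, 0),
    rt("amarogentin", "TAS2R46", "H1", 3.0e-5, 6.7e-5, 0.57),
    rt("amarogentin", "TAS2R46", "H2", NA, NA, 0),
    rt("amarogentin", "TAS2R46", "H3", 1.0e-4, 1.5e-4, 0.30),
    rt("quassin", "TAS2R30", "H1", 3.0e-8, 3.0e-7, 0.45),
    rt("quassin", "TAS2R30", "H2", 1.0e-6, 1.5e-6, 0.10),
    rt("quassin", "TAS2R46", "H1", 3.0e-5, 7.0e-5, 0.50),
    rt("quassin", "TAS2R46", "H2", NA, NA, 0),
    rt("quassin", "TAS2R46", "H3", 1.0e-4, 2.0e-4, 0.30),
    rt("grosheimin", "TAS2R43", "H1", 1.0e-5, 1.6e-5, 0.60),
    rt("grosheimin", "TAS2R43", "H2", 3.0e-6, 6.9e-6, 0.81),
    rt("grosheimin", "TAS2R43", "DEL", NA, NA, 0),
    rt("grosheimin", "TAS2R46", "H1", 1.0e-6, 5.6e-6, 0.87),
    rt("grosheimin", "TAS2R46", "H2", NA, NA, 0),
    rt("grosheimin", "TAS2R46", "H3", 3.0e-6, 7.6e-6, 0.50),
    rt("absinthin", "TAS2R30", "H1", 3.0e-7, 3.1e-6, 0.41),
    rt("absinthin", "TAS2R30", "H2", 1.0e-6, 1.3e-6, 0.15),
    rt("absinthin", "TAS2R46", "H1", 3.0e-6, 1.1e-5, 0.63),
    rt("absinthin", "TAS2R46", "H2", NA, NA, 0),
    rt("absinthin", "TAS2R46", "H3", 1.0e-5, 1.4e-5, 0.48),
    rt("cascarillin", "TAS2R30", "H1", 3.0e-5, 7.0e-5, 0.40),
    rt("cascarillin", "TAS2R30", "H2", 1.0e-4, 2.0e-4, 0.15),
    rt("cascarillin", "TAS2R46", "H1", 3.0e-5, 8.0e-5, 0.50),
    rt("cascarillin", "TAS2R46", "H2", NA, NA, 0),
    rt("cascarillin", "TAS2R46", "H3", 1.0e-4, 2.0e-4, 0.30),
    rt("quinine", "TAS2R30", "H1", 1.0e-5, 3.0e-5, 0.40),
    rt("quinine", "TAS2R30", "H2", 3.0e-5, 8.0e-5, 0.15),
    rt("quinine", "TAS2R31", "H1", 3.0e-5, 8.0e-5, 0.30),
    rt("quinine", "TAS2R31", "H2", 1.0e-5, 3.0e-5, 0.45),
    rt("quinine", "TAS2R31", "H3", NA, NA, 0),
    rt("quinine", "TAS2R31", "H4", 3.0e-5, 8.0e-5, 0.30),
    rt("quinine", "TAS2R43", "H1", 3.0e-5, 8.0e-5, 0.30),
    rt("quinine", "TAS2R43", "H2", 1.0e-5, 3.0e-5, 0.40),
    rt("quinine", "TAS2R43", "DEL", NA, NA, 0),
    rt("quinine", "TAS2R46", "H1", 1.0e-5, 3.0e-5, 0.50),
    rt("quinine", "TAS2R46", "H2", NA, NA, 0),
    rt("quinine", "TAS2R46", "H3", 3.0e-5, 8.0e-5, 0.30)
  )
  receptor_table <- calibrate_hill_n(receptor_table)

  # 12-step, 1.5-ratio series; starts give the published per-compound ranges
  psych_design <- data.frame(
    compound = c("absinthin", "amarogentin", "cascarillin", "grosheimin",
                 "quassin", "quinine"),
    start = c(2.3e-8, 3.5e-9, 4.6e-7, 5.8e-7, 1.2e-8, 4.6e-7),
    ratio = 1.5, n_steps = 12L, n_reps = 3L, guess = 0.25,
    det_shift = 0.15, slope_det = 8, slope_rec = 8,
    int_shift = 0.45, int_slope = 0.35,
    imax_mean = 80, imax_sd = 8, int_noise_sd = 4,
    stringsAsFactors = FALSE)

  # perceptual link, per compound (log10 scale); the absinthin/cascarillin
  # slopes compress in-vitro differences so that the two repulsion-phase
  # sensitive alleles are perceptually near-equivalent
  link <- data.frame(
    compound = psych_design$compound,
    offset = c(-5.748, 0, -4.768, 0.7, 0, -0.4),
    slope  = c(0.1, 1, 0.1, 1, 1, 1),
    subject_sd = c(0.15, 0.15, 0.15, 0.15, 0.15, 0.2),
    stringsAsFactors = FALSE)

  plate_design <- list(
    conc = c(1e-9, 3e-9, 1e-8, 3e-8, 1e-7, 3e-7, 1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 3e-4),
    n_days = 6L, n_pc_wells = 3L,
    day_sd = 0.15, noise_sd = 0.001, f0_mean = 1000, f0_sd = 100,
    artefact_amp = 0.05, pc_response = 1.0,
    ceiling = c(absinthin = 3e-4, amarogentin = 3e-4, cascarillin = 3e-4,
                grosheimin = 3e-4, quassin = 3e-4, quinine = 3e-5))

  inventory <- list(
    amarogentin = c("TAS2R1", "TAS2R4", "TAS2R39", "TAS2R43", "TAS2R46",
                    "TAS2R30", "TAS2R50"),
    grosheimin = c("TAS2R43", "TAS2R46"),
    absinthin = c("TAS2R30", "TAS2R46"),
    cascarillin = c("TAS2R30", "TAS2R46"),
    quassin = c("TAS2R30", "TAS2R46"),
    quinine = c("TAS2R30", "TAS2R31", "TAS2R43", "TAS2R46"))

  scenario(genes, sites, gene_haps, lrh_pool, receptor_table, link,
           psych_design, plate_design, inventory,
           n_subjects = n_subjects, seed = seed)
}

#' Paired two-locus scenarios with identical allele effect sizes
#'
#' Builds a minimal one-block, two-gene scenario in which each gene carries
#' one sensitive and one insensitive allele with the *same* activation
#' thresholds at both loci, arranged either in coupling phase (sensitive
#' alleles co-resident on one haplotype) or repulsion phase (each haplotype
#' carries exactly one gene's sensitive allele). In repulsion every subject
#' carries a sensitive allele, so the latent phenotype is constant up to
#' subject noise and genotype-phenotype association vanishes; in coupling,
#' insensitive-haplotype homozygotes form a distinct phenotype class.
#'
#' @param phase `"coupling"` or `"repulsion"`.
#' @param thr_sensitive,thr_insensitive activation thresholds (M).
#' @param freq frequency of the first pool haplotype (second gets the rest).
#' @param subject_sd subject noise, log10 units.
#' @param n_subjects cohort size.
#' @return A `tas2r_scenario` with a single compound `"bitterant"`.
#' @export
two_locus_scenario <- function(phase = c("coupling", "repulsion"),
                               thr_sensitive = 1e-6, thr_insensitive = 1e-5,
                               freq = 0.5, subject_sd = 0.25,
                               n_subjects = 48L) {
  phase <- match.arg(phase)
  genes <- data.frame(
    gene = c("GENEA", "GENEB"), chrom = "chr12", block = "AB",
    pos = c(1e6, 1.03e6), cnv = FALSE, stringsAsFactors = FALSE)
  sites <- data.frame(
    site_id = c("GENEA_s1", "GENEB_s1"), gene = c("GENEA", "GENEB"),
    chrom = "chr12", pos = c(1e6 + 150, 1.03e6 + 150),
    ref = "A", alt = "G", consequence = "missense", stringsAsFactors = FALSE)
  gene_haps <- list(GENEA = hap_vectors(2, "A", "G"),
                    GENEB = hap_vectors(2, "A", "G"))
  comp <- if (phase == "coupling") {
    list(c(GENEA = "H1", GENEB = "H1"), c(GENEA = "H2", GENEB = "H2"))
  } else {
    list(c(GENEA = "H1", GENEB = "H2"), c(GENEA = "H2", GENEB = "H1"))
  }
  names(comp) <- c("LRH1", "LRH2")
  lrh_pool <- list(AB = list(
    freq = stats::setNames(c(freq, 1 - freq), names(comp)), comp = comp))
  receptor_table <- data.frame(
    compound = "bitterant", gene = rep(c("GENEA", "GENEB"), each = 2),
    allele = rep(c("H1", "H2"), 2),
    activation_threshold = rep(c(thr_sensitive, thr_insensitive), 2),
    ec50 = rep(c(thr_sensitive, thr_insensitive), 2) * 10,
    amplitude = rep(c(0.6, 0.3), 2), hill_n = 1, stringsAsFactors = FALSE)
  receptor_table <- calibrate_hill_n(receptor_table)
  link <- data.frame(compound = "bitterant", offset = 0, slope = 1,
                     subject_sd = subject_sd, stringsAsFactors = FALSE)
  psych_design <- data.frame(
    compound = "bitterant", start = thr_sensitive / 8, ratio = 1.5,
    n_steps = 12L, n_reps = 3L, guess = 0.25, det_shift = 0.15,
    slope_det = 8, slope_rec = 8, int_shift = 0.45, int_slope = 0.35,
    imax_mean = 80, imax_sd = 8, int_noise_sd = 4, stringsAsFactors = FALSE)
  plate_design <- list(
    conc = c(1e-9, 3e-9, 1e-8, 3e-8, 1e-7, 3e-7, 1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 3e-4),
    n_days = 6L, n_pc_wells = 3L, day_sd = 0.15, noise_sd = 0.001,
    f0_mean = 1000, f0_sd = 100, artefact_amp = 0.05, pc_response = 1.0,
    ceiling = c(bitterant = 3e-4))
  scenario(genes, sites, gene_haps, lrh_pool, receptor_table, link,
           psych_design, plate_design,
           inventory = list(bitterant = c("GENEA", "GENEB")),
           n_subjects = n_subjects)
}
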