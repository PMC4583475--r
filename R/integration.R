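#' Classify receptor alleles by sensitivity and phenotype relevance
#'
#' Alleles never significantly activated are `nonfunctional`. Activated
#' alleles are classed within (compound, gene) by the ratio of their
#' activation threshold to the gene's best threshold for that compound:
#' <= `sensitive_ratio` sensitive, <= `intermediate_ratio` intermediate,
#' else insensitive. Independently, an allele is *phenotype-explanatory*
#' iff its activation threshold lies at or below the top of the subjects'
#' recognition-threshold range — i.e. the receptor responds in the
#' concentration range perceived as bitter.
#'
#' @param fits dose-response table ([dose_response_table()] or a manual
#'   data.frame with gene, allele, compound, threshold_conc, ec50,
#'   amplitude, activated).
#' @param subject_range named list compound -> c(min, max) recognition
#'   thresholds (M), or a single c(min, max) applied to all compounds.
#' @param sensitive_ratio,intermediate_ratio class boundaries (threshold
#'   ratio to the gene's best allele).
#' @param common_alleles optional data.frame (gene, allele) of common
#'   alleles that must be covered; missing fits are reported in the
#'   `gaps` attribute rather than silently passed.
#' @return the table with `class` and `explanatory` columns.
#' @export
classify_alleles <- function(fits, subject_range = NULL,
                             sensitive_ratio = 3, intermediate_ratio = 30,
                             common_alleles = NULL) {
  f <- fits
  f$class <- "nonfunctional"
  f$explanatory <- FALSE
  for (cm in unique(f$compound)) {
    rng <- if (is.null(subject_range)) NULL
    else if (is.list(subject_range)) subject_range[[cm]] else subject_range
    sel <- f$compound == cm
    for (g in unique(f$gene[sel])) {
      gi <- which(sel & f$gene == g & f$activated & !is.na(f$threshold_conc))
      if (length(gi) == 0) next
      best <- min(f$threshold_conc[gi])
      ratio <- f$threshold_conc[gi] / best
      f$class[gi] <- ifelse(ratio <= sensitive_ratio, "sensitive",
                            ifelse(ratio <= intermediate_ratio,
                                   "intermediate", "insensitive"))
      if (!is.null(rng)) {
        f$explanatory[gi] <- f$threshold_conc[gi] <= max(rng)
      }
    }
  }
  gaps <- NULL
  if (!is.null(common_alleles)) {
    have <- paste(f$gene, f$allele)
    want <- paste(common_alleles$gene, common_alleles$allele)
    gaps <- common_alleles[!(want %in% have), , drop = FALSE]
    if (nrow(gaps) > 0) {
      warning(sprintf("no dose-response fit for common allele(s): %s",
                      paste(gaps$gene, gaps$allele, collapse = ", ")))
    }
  }
  structure(f, gaps = gaps)
}

# sensitive alleles per gene for one compound, from a classified table
sensitive_map <- function(rft, compound) {
  s <- rft[rft$compound == compound & rft$class == "sensitive", , drop = FALSE]
  split(s$allele, s$gene)
}

#' Linkage-phase summary of sensitive alleles on long-range haplotypes
#'
#' For one compound and a pair (or set) of genes within a block: annotates
#' every common long-range haplotype with the genes whose sensitive allele
#' it carries, counts per subject the carried LRH copies bearing at least
#' one sensitive allele, and derives the phase mode — `single_locus` when
#' only one gene has a sensitive allele; `repulsion` when every common LRH
#' carries exactly one gene's sensitive allele; `coupling` when the LRHs
#' carrying one gene's sensitive allele are a subset of those carrying the
#' other's (with at least one carrying both); otherwise `mixed`.
#'
#' @param cohort a `tas2r_cohort` (true phase), or a list with `lrh` block
#'   label matrices and a `lrh_comp` map (block -> LRH -> gene alleles).
#' @param rft classified receptor table from [classify_alleles()].
#' @param compound compound name.
#' @param block block id (default: the block containing the sensitive
#'   genes; must be unique).
#' @param min_freq frequency above which an LRH counts as common.
#' @return list of class `phase_summary`: `compound`, `genes`,
#'   `lrh_content` (data.frame LRH, freq, sensitive genes carried),
#'   `dosage` (per-subject sensitive copy count), `fractions` (population
#'   fractions by count, sums to 1), `phase_mode`.
#' @export
phase_summary <- function(cohort, rft, compound, block = NULL,
                          min_freq = 0.05) {
  smap <- sensitive_map(rft, compound)
  genes <- names(smap)
  if (length(genes) == 0) stop("no sensitive alleles for this compound",
                               call. = FALSE)
  sc <- cohort$scenario
  cand <- unique(sc$genes$block[sc$genes$gene %in% genes])
  if (is.null(block)) {
    if (length(cand) != 1) {
      stop("sensitive genes span several blocks; pass `block`", call. = FALSE)
    }
    block <- cand
  }
  labs <- cohort$lrh[[block]]
  freq <- table(labs) / length(labs)
  common <- names(freq)[freq >= min_freq]
  # which genes' sensitive alleles each LRH carries (needs compositions)
  comp_of <- function(lab) {
    comp <- sc$lrh_pool[[block]]$comp[[lab]]
    if (is.null(comp)) return(NULL)   # rare haplotype, unknown composition
    comp
  }
  carries <- function(lab) {
    comp <- comp_of(lab)
    if (is.null(comp)) {
      # rare label: fall back to the gene_hap matrices for carriage
      return(NA)
    }
    missing_g <- setdiff(genes, names(comp))
    if (length(missing_g) > 0) {
      stop(sprintf("LRH %s lacks annotation for gene(s): %s", lab,
                   paste(missing_g, collapse = ", ")), call. = FALSE)
    }
    genes[vapply(genes, function(g) comp[[g]] %in% smap[[g]], logical(1))]
  }
  lrh_content <- data.frame(lrh = common, freq = as.numeric(freq[common]),
                            sensitive = vapply(common, function(l) {
                              cg <- carries(l)
                              if (all(is.na(cg))) NA_character_
                              else paste(cg, collapse = ",")
                            }, character(1)), stringsAsFactors = FALSE)
  # per-subject dosage, from actual carried gene alleles (covers rare LRHs)
  sens_copy <- matrix(FALSE, length(cohort$subjects), 2)
  for (g in genes) {
    sens_copy <- sens_copy | matrix(cohort$gene_hap[[g]] %in% smap[[g]],
                                    ncol = 2)
  }
  dosage <- rowSums(sens_copy)
  fractions <- table(factor(dosage, 0:2)) / length(dosage)
  n_sens <- vapply(common, function(l) {
    cg <- carries(l)
    if (all(is.na(cg))) NA_integer_ else length(cg)
  }, integer(1))
  known <- !is.na(n_sens)
  phase_mode <- if (length(genes) == 1) "single_locus"
  else if (all(n_sens[known] == 1)) "repulsion"
  else {
    sets <- lapply(genes, function(g)
      common[known][vapply(common[known], function(l) g %in% carries(l),
                           logical(1))])
    both <- Reduce(intersect, sets)
    nested <- any(vapply(seq_along(sets), function(i)
      all(sets[[i]] %in% unlist(sets[-i])), logical(1)))
    if (length(both) > 0 && nested) "coupling" else "mixed"
  }
  structure(list(compound = compound, genes = genes, block = block,
                 lrh_content = lrh_content, dosage = dosage,
                 fractions = as.numeric(fractions),
                 phase_mode = phase_mode),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf("phase summary (%s, block %s): mode %s; genes %s\n",
              x$compound, x$block, x$phase_mode,
              paste(x$genes, collapse = ", ")))
  cat(sprintf("  sensitive-copy fractions 0/1/2: %s\n",
              paste(sprintf("%.2f", x$fractions), collapse = "/")))
  invisible(x)
}

#' Candidate causal-locus filter
#'
#' Intersects, per compound, (a) genes lying in blocks with
#' experiment-wide-significant association signals, (b) genes listed as
#' responsive in the receptor-agonist inventory, and (c) genes harbouring
#' phenotype-explanatory alleles, and classifies each gene: `causal`
#' (all three), `linked_passenger` (in a significant block but failing the
#' functional criteria), `phase_masked` (functional and explanatory but
#' without association signal, while its sensitive alleles sit in
#' repulsion phase), or `unexplained`.
#'
#' @param assoc association results from [scan_associations()] (block or
#'   gene level results used for significance; must carry `unit`,
#'   `compound`, `significant_experimentwide`).
#' @param rft classified receptor table ([classify_alleles()]).
#' @param inventory named list compound -> responsive genes.
#' @param gene_blocks data.frame (gene, block) mapping genes to blocks.
#' @param phase_modes optional named list compound -> [phase_summary()]
#'   used for the `phase_masked` call.
#' @return data.frame (compound, gene, block, in_significant_block,
#'   in_inventory, explanatory, classification).
#' @export
candidate_filter <- function(assoc, rft, inventory, gene_blocks,
                             phase_modes = NULL) {
  out <- list(); k <- 0L
  for (cm in unique(rft$compound)) {
    sig_units <- unique(assoc$unit[assoc$compound == cm &
                                     assoc$significant_experimentwide])
    sig_blocks <- unique(c(
      sig_units[sig_units %in% gene_blocks$block],
      gene_blocks$block[gene_blocks$gene %in% sig_units]))
    inv <- inventory[[cm]] %||% character(0)
    for (g in unique(rft$gene[rft$compound == cm])) {
      blk <- gene_blocks$block[gene_blocks$gene == g][1]
      in_sig <- !is.na(blk) && blk %in% sig_blocks
      in_inv <- g %in% inv
      expl <- any(rft$explanatory[rft$compound == cm & rft$gene == g])
      has_sens <- any(rft$class[rft$compound == cm & rft$gene == g] ==
                        "sensitive")
      cls <- if (in_sig && in_inv && expl) "causal"
      else if (in_sig) "linked_passenger"
      else if (in_inv && has_sens) {
        # functional variation without an association signal: masked when
        # the sensitive alleles sit in repulsion phase (perception may sit
        # below in-vitro activation, so explanatory status is not required)
        pm <- if (!is.null(phase_modes) && !is.null(phase_modes[[cm]]))
          phase_modes[[cm]]$phase_mode else NA_character_
        if (identical(pm, "repulsion")) "phase_masked" else "unexplained"
      }
      else "unexplained"
      k <- k + 1L
      out[[k]] <- data.frame(compound = cm, gene = g, block = blk,
                             in_significant_block = in_sig,
                             in_inventory = in_inv, explanatory = expl,
                             classification = cls, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
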