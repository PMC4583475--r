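#' Sample a phased synthetic cohort
#'
#' Draws, for every subject and every haplotype block, two long-range
#' haplotypes i.i.d. from the block's pool (random mating). The remainder
#' probability mass (1 - sum of pool frequencies) yields rare haplotypes,
#' generated by mutating a pool haplotype at one random site so allele sets
#' stay closed. Gene-level haplotypes, SNP genotypes and copy numbers are
#' then derived deterministically; whole-gene deletion haplotypes set copy
#' number and blank the deleted copy's site alleles.
#'
#' @param scenario a `tas2r_scenario`.
#' @param n_subjects number of diploid subjects (default from scenario).
#' @param seed integer seed; identical (scenario, n_subjects, seed) give
#'   identical cohorts.
#' @return An object of class `tas2r_cohort` with the true phase retained:
#'   `lrh` (block -> n x 2 LRH labels), `gene_hap` (gene -> n x 2 haplotype
#'   labels, `"DEL"` possible), and per-copy site allele matrices.
#' @export
sample_cohort <- function(scenario, n_subjects = scenario$n_subjects,
                          seed = scenario$seed) {
  validate_scenario(scenario)
  stopifnot(n_subjects >= 1)
  n <- as.integer(n_subjects)
  subjects <- sprintf("S%04d", seq_len(n))
  sites <- scenario$sites
  gene_sites <- split(seq_len(nrow(sites)), sites$gene)

  lrh <- list(); gene_hap <- list()
  A <- list(matrix(NA_character_, n, nrow(sites)),
            matrix(NA_character_, n, nrow(sites)))
  for (g in scenario$genes$gene) {
    gene_hap[[g]] <- matrix(NA_character_, n, 2)
  }

  with_local_seed(seed, {
    for (b in names(scenario$lrh_pool)) {
      pool <- scenario$lrh_pool[[b]]
      bg <- scenario$genes$gene[scenario$genes$block == b]
      f <- pool$freq
      p_rare <- max(0, 1 - sum(f))
      labs <- sample(c(names(f), ".rare"), 2L * n, replace = TRUE,
                     prob = c(f, p_rare))
      # per-draw gene haplotype composition and rare-site mutations
      comp_of <- vector("list", 2L * n)
      for (k in seq_len(2L * n)) {
        if (labs[k] != ".rare") {
          comp_of[[k]] <- pool$comp[[labs[k]]]
        } else {
          base <- sample(names(f), 1L, prob = f / sum(f))
          comp <- pool$comp[[base]]
          # mutable sites: sites of non-deleted genes in this block
          ok_genes <- bg[comp[bg] != "DEL" & lengths(scenario$gene_haps[bg]) > 0]
          ok_genes <- ok_genes[vapply(ok_genes, function(g)
            length(gene_sites[[g]] %||% integer(0)) > 0, logical(1))]
          if (length(ok_genes) == 0) {
            comp_of[[k]] <- comp
            labs[k] <- paste0("rare:", base)
            next
          }
          g <- if (length(ok_genes) == 1) ok_genes else sample(ok_genes, 1L)
          gsites <- gene_sites[[g]]
          j <- if (length(gsites) == 1) 1L else sample(length(gsites), 1L)
          vec <- scenario$gene_haps[[g]][[comp[[g]]]]
          vec[j] <- ifelse(vec[j] == sites$ref[gsites[j]],
                           sites$alt[gsites[j]], sites$ref[gsites[j]])
          # relabel: existing haplotype if the flip recreates one
          match_h <- NA_character_
          for (h in names(scenario$gene_haps[[g]])) {
            if (identical(scenario$gene_haps[[g]][[h]], vec)) match_h <- h
          }
          hl <- if (!is.na(match_h)) match_h else
            paste0("r_", g, "_", paste(vec, collapse = ""))
          comp[[g]] <- hl
          attr(comp, "rare_alleles") <- stats::setNames(list(vec), g)
          comp_of[[k]] <- comp
          labs[k] <- paste0("rare:", base, ":", g, ":", hl)
        }
      }
      lrh[[b]] <- matrix(labs, n, 2)
      for (copy in 1:2) {
        for (i in seq_len(n)) {
          comp <- comp_of[[(copy - 1L) * n + i]]
          rare <- attr(comp, "rare_alleles")
          for (g in bg) {
            h <- comp[[g]]
            gene_hap[[g]][i, copy] <- h
            gsites <- gene_sites[[g]] %||% integer(0)
            if (length(gsites) == 0) next
            if (h == "DEL") {
              A[[copy]][i, gsites] <- NA_character_
            } else if (!is.null(rare) && g %in% names(rare)) {
              A[[copy]][i, gsites] <- rare[[g]]
            } else {
              A[[copy]][i, gsites] <- scenario$gene_haps[[g]][[h]]
            }
          }
        }
      }
    }
  })

  structure(list(scenario = scenario, subjects = subjects, lrh = lrh,
                 gene_hap = gene_hap, alleles = A),
            class = "tas2r_cohort")
}

#' @export
print.tas2r_cohort <- function(x, ...) {
  cat(sprintf("tas2r_cohort: %d subjects, %d genes, %d sites, %d blocks\n",
              length(x$subjects), nrow(x$scenario$genes),
              nrow(x$scenario$sites), length(x$lrh)))
  invisible(x)
}

#' Site-level genotype matrix of a cohort
#'
#' @param cohort a `tas2r_cohort`.
#' @return character matrix subjects x sites; entries are unordered allele
#'   pairs `"A/G"` (sorted), a single allele for hemizygous subjects
#'   (copy number 1), or `NA` where both copies are deleted.
#' @export
genotype_matrix <- function(cohort) {
  a1 <- cohort$alleles[[1]]; a2 <- cohort$alleles[[2]]
  gm <- matrix(NA_character_, nrow(a1), ncol(a1),
               dimnames = list(cohort$subjects, cohort$scenario$sites$site_id))
  both <- !is.na(a1) & !is.na(a2)
  gm[both] <- paste(pmin(a1[both], a2[both]), pmax(a1[both], a2[both]), sep = "/")
  only1 <- !is.na(a1) & is.na(a2)
  gm[only1] <- a1[only1]
  only2 <- is.na(a1) & !is.na(a2)
  gm[only2] <- a2[only2]
  gm
}

#' Copy-number table of a cohort
#'
#' @param cohort a `tas2r_cohort`.
#' @return data.frame (subject, gene, copies) for CNV-capable genes.
#' @export
copy_number_table <- function(cohort) {
  cnv <- cohort$scenario$genes$gene[cohort$scenario$genes$cnv]
  out <- NULL
  for (g in cnv) {
    cp <- 2L - rowSums(cohort$gene_hap[[g]] == "DEL")
    out <- rbind(out, data.frame(subject = cohort$subjects, gene = g,
                                 copies = cp, stringsAsFactors = FALSE))
  }
  out
}

#' Subject latent sensitivities
#'
#' For every subject and compound, the latent log10 recognition threshold is
#' `offset + slope * log10(min activation threshold over carried functional
#' alleles) + N(0, subject_sd)`. Subjects carrying no functional allele of
#' any assayed receptor default to the top of the compound's tested series
#' (perception via receptors outside the assayed set).
#'
#' @param cohort a `tas2r_cohort`.
#' @param seed integer seed for the subject noise.
#' @return data.frame (subject, compound, latent_log10).
#' @export
latent_sensitivity <- function(cohort, seed = cohort$scenario$seed) {
  sc <- cohort$scenario
  rt <- sc$receptor_table
  rt <- rt[rt$amplitude > 0 & !is.na(rt$activation_threshold), , drop = FALSE]
  out <- NULL
  for (cm in sc$psych_design$compound) {
    pd <- sc$psych_design[sc$psych_design$compound == cm, ]
    lk <- sc$link[sc$link$compound == cm, ]
    top_log10 <- log10(pd$start * pd$ratio^(pd$n_steps - 1))
    rti <- rt[rt$compound == cm, ]
    thr_map <- stats::setNames(rti$activation_threshold,
                               paste(rti$gene, rti$allele, sep = "-"))
    mu <- vapply(seq_along(cohort$subjects), function(i) {
      carried <- unlist(lapply(unique(rti$gene), function(g)
        paste(g, cohort$gene_hap[[g]][i, ], sep = "-")))
      thr <- thr_map[intersect(carried, names(thr_map))]
      if (length(thr) == 0) top_log10
      else lk$offset + lk$slope * log10(min(thr))
    }, numeric(1))
    noise <- with_local_seed(child_seed(seed, paste0("latent_", cm)),
                             stats::rnorm(length(mu), 0, lk$subject_sd))
    out <- rbind(out, data.frame(subject = cohort$subjects, compound = cm,
                                 latent_log10 = mu + noise,
                                 stringsAsFactors = FALSE))
  }
  out
}
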