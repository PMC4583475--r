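#' Phase every gene of a genotype matrix
#'
#' Runs [phase_em()] per gene over that gene's sites, using copy-number
#' calls (where available) so hemizygous subjects contribute a single
#' observed haplotype and zero-copy subjects the deletion diplotype.
#'
#' @param gm genotype matrix (subjects x sites) as from [genotype_matrix()].
#' @param sites site table with columns `site_id` and `gene`.
#' @param cn optional copy-number data.frame (subject, gene, copies).
#' @param ... passed to [phase_em()].
#' @return named list gene -> [phase_em()] result (genes with no sites are
#'   skipped).
#' @export
phase_genes <- function(gm, sites, cn = NULL, ...) {
  res <- list()
  for (g in unique(sites$gene)) {
    sid <- sites$site_id[sites$gene == g]
    sid <- intersect(sid, colnames(gm))
    if (length(sid) == 0) next
    copies <- rep(2L, nrow(gm))
    if (!is.null(cn) && g %in% cn$gene) {
      cni <- cn[cn$gene == g, ]
      copies <- cni$copies[match(rownames(gm), cni$subject)]
      copies[is.na(copies)] <- 2L
    }
    res[[g]] <- phase_em(gm[, sid, drop = FALSE], copies = copies, ...)
  }
  res
}

#' Gene-level diplotype matrix from per-gene phasing
#'
#' Converts per-gene phased results into a subjects x genes matrix of
#' unordered gene-haplotype-name pairs (`"H1/H2"`, `"DEL/H1"`, ...), the
#' multi-allelic marker representation used for block-scope phasing and
#' gene-level LD.
#'
#' @param gene_results output of [phase_genes()].
#' @param genes genes to include (default: all phased).
#' @return character matrix, `NA` where a subject was unphased.
#' @export
gene_diplotype_matrix <- function(gene_results, genes = names(gene_results)) {
  genes <- intersect(genes, names(gene_results))
  n <- nrow(gene_results[[genes[1]]]$phase)
  m <- matrix(NA_character_, n, length(genes), dimnames = list(NULL, genes))
  for (g in genes) {
    r <- gene_results[[g]]
    nm <- stats::setNames(r$haplotypes$name, r$haplotypes$haplotype)
    h1 <- nm[r$phase$hap1]; h2 <- nm[r$phase$hap2]
    ok <- !is.na(h1) & !is.na(h2)
    m[ok, g] <- paste(pmin(h1[ok], h2[ok]), pmax(h1[ok], h2[ok]), sep = "/")
  }
  m
}

#' Phase long-range haplotypes across a block
#'
#' Treats each gene's haplotype as one multi-allelic marker (deletion as
#' the allele `"DEL"`) and runs [phase_em()] across the block's genes,
#' yielding the block's long-range haplotypes with frequencies (named
#' `H-LR1`, `H-LR2`, ... by descending frequency) and per-subject phased
#' pairs.
#'
#' @param diplo gene-level diplotype matrix from [gene_diplotype_matrix()].
#' @param block_genes ordered genes of the block.
#' @param ... passed to [phase_em()].
#' @return a [phase_em()] result; long-range haplotype strings join gene
#'   haplotype names with `"|"` in `block_genes` order.
#' @export
phase_block <- function(diplo, block_genes, ...) {
  block_genes <- intersect(block_genes, colnames(diplo))
  phase_em(diplo[, block_genes, drop = FALSE], prefix = "H-LR", ...)
}

#' True haplotype matrix of a synthetic cohort
#'
#' Stacks the two chromosome copies of every subject into a 2n x units
#' matrix — site alleles at `level = "snp"` (NA on deleted copies), gene
#' haplotype labels (including `"DEL"`) at `level = "gene"`, or long-range
#' haplotype labels at `level = "block"`.
#'
#' @param cohort a `tas2r_cohort`.
#' @param level `"snp"`, `"gene"` or `"block"`.
#' @return character matrix with 2n rows (copy 1 block then copy 2).
#' @export
true_haplotype_matrix <- function(cohort, level = c("snp", "gene", "block")) {
  level <- match.arg(level)
  if (level == "snp") {
    m <- rbind(cohort$alleles[[1]], cohort$alleles[[2]])
    colnames(m) <- cohort$scenario$sites$site_id
  } else if (level == "gene") {
    genes <- cohort$scenario$genes$gene
    m <- vapply(genes, function(g) c(cohort$gene_hap[[g]][, 1],
                                     cohort$gene_hap[[g]][, 2]),
                character(2L * length(cohort$subjects)))
    colnames(m) <- genes
  } else {
    blocks <- names(cohort$lrh)
    m <- vapply(blocks, function(b) c(cohort$lrh[[b]][, 1],
                                      cohort$lrh[[b]][, 2]),
                character(2L * length(cohort$subjects)))
    colnames(m) <- blocks
  }
  m
}
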