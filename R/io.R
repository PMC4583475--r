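#' Write a cohort as a multi-sample VCF (v4.2)
#'
#' One record per coding SNP (1-based positions, GT field; phased `|`
#' separators since the synthetic truth is phased) plus one symbolic
#' `<DEL>` record per CNV-capable gene encoding the whole-gene deletion
#' allele. Hemizygous subjects get haploid GT at the deleted gene's sites;
#' zero-copy subjects get `.`.
#'
#' @param cohort a `tas2r_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  sc <- cohort$scenario
  n <- length(cohort$subjects)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bitterhap",
           sprintf("##contig=<ID=%s,length=250000000>", unique(sc$sites$chrom)),
           "##ALT=<ID=DEL,Description=\"Whole-gene deletion\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cohort$subjects), collapse = "\t"))
  a1 <- cohort$alleles[[1]]; a2 <- cohort$alleles[[2]]
  recs <- character(0)
  for (j in seq_len(nrow(sc$sites))) {
    st <- sc$sites[j, ]
    code <- function(x) ifelse(is.na(x), ".", ifelse(x == st$ref, "0", "1"))
    c1 <- code(a1[, j]); c2 <- code(a2[, j])
    gt <- ifelse(c1 == "." & c2 == ".", ".",
                 ifelse(c1 == ".", c2, ifelse(c2 == ".", c1,
                                              paste(c1, c2, sep = "|"))))
    recs <- c(recs, paste(c(st$chrom, format(st$pos, scientific = FALSE),
                            st$site_id, st$ref, st$alt, ".", "PASS",
                            sprintf("GENE=%s;CSQ=%s", st$gene, st$consequence),
                            "GT", gt), collapse = "\t"))
  }
  for (g in sc$genes$gene[sc$genes$cnv]) {
    gi <- sc$genes[sc$genes$gene == g, ]
    d1 <- ifelse(cohort$gene_hap[[g]][, 1] == "DEL", "1", "0")
    d2 <- ifelse(cohort$gene_hap[[g]][, 2] == "DEL", "1", "0")
    recs <- c(recs, paste(c(gi$chrom, format(gi$pos, scientific = FALSE),
                            paste0(g, "_del"), "N", "<DEL>", ".", "PASS",
                            sprintf("SVTYPE=DEL;GENE=%s", g), "GT",
                            paste(d1, d2, sep = "|")), collapse = "\t"))
  }
  ord <- order(sub("chr", "", sapply(strsplit(recs, "\t"), `[`, 1)),
               as.numeric(sapply(strsplit(recs, "\t"), `[`, 2)))
  writeLines(c(hdr, recs[ord]), path)
  invisible(path)
}

#' Read genotypes and copy numbers from a VCF
#'
#' Parses a multi-sample VCF (via vcfR) into the site table, the unordered
#' genotype matrix used by [phase_genes()], and copy-number calls from
#' symbolic `<DEL>` records.
#'
#' @param path VCF file.
#' @return list: `sites` (site_id, gene, chrom, pos, ref, alt,
#'   consequence), `genotypes` (subjects x sites character matrix),
#'   `copy_number` (subject, gene, copies; NULL if no `<DEL>` records).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  info <- vcfR::extract.info(v, "GENE")
  csq <- vcfR::extract.info(v, "CSQ")
  is_del <- fix$ALT == "<DEL>"
  subjects <- colnames(gt)
  cn <- NULL
  if (any(is_del)) {
    rows <- which(is_del)
    cn <- do.call(rbind, lapply(rows, function(r) {
      alt_count <- vapply(strsplit(gt[r, ], "[|/]"), function(x)
        sum(x == "1"), integer(1))
      data.frame(subject = subjects, gene = info[r],
                 copies = 2L - alt_count, stringsAsFactors = FALSE)
    }))
  }
  snp <- which(!is_del)
  sites <- data.frame(site_id = fix$ID[snp], gene = info[snp],
                      chrom = fix$CHROM[snp], pos = as.numeric(fix$POS[snp]),
                      ref = fix$REF[snp], alt = fix$ALT[snp],
                      consequence = csq[snp], stringsAsFactors = FALSE)
  geno <- matrix(NA_character_, length(subjects), length(snp),
                 dimnames = list(subjects, fix$ID[snp]))
  for (i in seq_along(snp)) {
    r <- snp[i]
    al <- c(fix$REF[r], fix$ALT[r])
    parts <- strsplit(gt[r, ], "[|/]")
    geno[, i] <- vapply(parts, function(x) {
      x <- x[x != "."]
      if (length(x) == 0) return(NA_character_)
      a <- al[as.integer(x) + 1L]
      if (length(a) == 1) a else paste(sort(a), collapse = "/")
    }, character(1))
  }
  list(sites = sites, genotypes = geno, copy_number = cn)
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Serialise a scenario to JSON
#'
#' @param scenario a `tas2r_scenario`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
scenario_to_json <- function(scenario, path) {
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
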