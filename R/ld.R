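#' Pairwise linkage disequilibrium between two multi-allelic loci
#'
#' From a joint haplotype count table, computes the frequency-weighted
#' multi-allelic D' (`sum_ij p_i q_j |D'_ij|`), the chi-square-based
#' r-squared (`chisq / (N * min(k-1, l-1))`, the squared Cramer's V), and a
#' seeded Monte-Carlo chi-square independence p-value. For biallelic loci
#' these reduce to the classical D' and r².
#'
#' @param counts k x l matrix of joint haplotype counts (k, l >= 2 before
#'   collapsing; alleles with zero marginal count are dropped).
#' @param n_perm Monte-Carlo draws for the p-value (0 for the asymptotic
#'   chi-square p).
#' @param seed integer seed for the Monte-Carlo draw.
#' @return list with `d_prime`, `r2`, `p`, `n`.
#' @export
pairwise_ld <- function(counts, n_perm = 10000L, seed = 1L) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least two alleles at each locus after collapsing",
         call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("empty count table", call. = FALSE)
  pj <- counts / n
  p <- rowSums(pj); q <- colSums(pj)
  dmat <- pj - outer(p, q)
  dmax <- matrix(0, nrow(pj), ncol(pj))
  for (i in seq_along(p)) for (j in seq_along(q)) {
    dmax[i, j] <- if (dmat[i, j] >= 0) {
      min(p[i] * (1 - q[j]), (1 - p[i]) * q[j])
    } else {
      min(p[i] * q[j], (1 - p[i]) * (1 - q[j]))
    }
  }
  dp <- abs(dmat) / dmax
  dp[dmax == 0] <- 0
  d_prime <- sum(outer(p, q) * dp)
  expct <- outer(p, q) * n
  chisq <- sum((counts - expct)^2 / expct)
  r2 <- chisq / (n * min(nrow(counts) - 1, ncol(counts) - 1))
  pval <- if (n_perm > 0) {
    with_local_seed(seed, suppressWarnings(
      stats::chisq.test(counts, simulate.p.value = TRUE, B = n_perm)$p.value))
  } else {
    suppressWarnings(stats::chisq.test(counts)$p.value)
  }
  list(d_prime = unname(d_prime), r2 = unname(min(1, r2)),
       p = unname(pval), n = n)
}

# joint haplotype counts for two columns of a (2n x units) haplotype matrix
joint_counts <- function(h1, h2) {
  ok <- !is.na(h1) & !is.na(h2)
  table(factor(h1[ok]), factor(h2[ok]))
}

# frequency of the second most common allele (generalised MAF)
second_allele_freq <- function(x) {
  tb <- sort(table(x[!is.na(x)]), decreasing = TRUE)
  if (length(tb) < 2) return(0)
  as.numeric(tb[2] / sum(tb))
}

#' Pairwise LD matrices across common units
#'
#' Computes [pairwise_ld()] for every within-chromosome pair of common
#' units (second-allele frequency >= `min_freq`; monomorphic or rare units
#' are excluded and recorded in the `dropped` attribute). At `"gene"` level
#' each gene's haplotype is one multi-allelic marker.
#'
#' @param hapmat 2n x units haplotype matrix (e.g.
#'   [true_haplotype_matrix()], or stacked phased haplotypes).
#' @param units data.frame with columns `unit` and `chrom`, in map order.
#' @param min_freq common-variant frequency filter (default 0.05).
#' @param n_perm,seed Monte-Carlo settings per pair.
#' @return list of symmetric matrices `d_prime`, `r2`, `p` over kept units
#'   (NA across chromosomes), plus the kept `units`.
#' @export
ld_matrix <- function(hapmat, units, min_freq = 0.05, n_perm = 2000L,
                      seed = 1L) {
  stopifnot(all(units$unit %in% colnames(hapmat)))
  keep <- vapply(units$unit, function(u)
    second_allele_freq(hapmat[, u]) >= min_freq, logical(1))
  dropped <- units$unit[!keep]
  units <- units[keep, , drop = FALSE]
  m <- nrow(units)
  dmat <- r2m <- pm <- matrix(NA_real_, m, m,
                              dimnames = list(units$unit, units$unit))
  diag(dmat) <- diag(r2m) <- 1; diag(pm) <- 0
  if (m >= 2) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (units$chrom[i] != units$chrom[j]) next
      cc <- joint_counts(hapmat[, units$unit[i]], hapmat[, units$unit[j]])
      # a pair can turn monomorphic after pairwise complete-case removal
      # (e.g. two co-deleted genes); left NA
      ld <- tryCatch(pairwise_ld(cc, n_perm = n_perm,
                                 seed = child_seed(seed, paste(i, j))),
                     error = function(e) NULL)
      if (is.null(ld)) next
      dmat[i, j] <- dmat[j, i] <- ld$d_prime
      r2m[i, j] <- r2m[j, i] <- ld$r2
      pm[i, j] <- pm[j, i] <- ld$p
    }
  }
  structure(list(d_prime = dmat, r2 = r2m, p = pm, units = units),
            dropped = dropped)
}

#' Mean pairwise LD over a set of units
#'
#' @param ld result of [ld_matrix()].
#' @param units subset of unit names (default all kept units).
#' @return named numeric: mean off-diagonal `d_prime` and `r2`.
#' @export
ld_region_means <- function(ld, units = ld$units$unit) {
  units <- intersect(units, ld$units$unit)
  d <- ld$d_prime[units, units, drop = FALSE]
  r <- ld$r2[units, units, drop = FALSE]
  off <- upper.tri(d)
  c(d_prime = mean(d[off], na.rm = TRUE), r2 = mean(r[off], na.rm = TRUE))
}

#' Haplotype block partition by the four-gamete rule
#'
#' Collapses each unit to major-allele-vs-rest, declares recombination
#' evidence between a pair of units when all four two-locus gametes reach
#' the frequency cutoff, and builds blocks greedily left-to-right along
#' each chromosome as maximal contiguous runs in which *no* within-run pair
#' shows recombination evidence. Manual overrides (unit -> forced block
#' label) win over the algorithm; blocks stay contiguous.
#'
#' @param hapmat 2n x units haplotype matrix (phased).
#' @param units data.frame with columns `unit`, `chrom`, `pos`, ordered by
#'   position within chromosome (validated).
#' @param cutoff minimum frequency of the rarest gamete (default 0.05).
#' @param overrides optional named character vector unit -> block label.
#' @param min_freq units whose second most common allele falls below this
#'   frequency (monomorphic or near-monomorphic units, which can never
#'   show recombination evidence) are excluded; they are listed in the
#'   `excluded` attribute.
#' @return data.frame (unit, chrom, pos, block) — the partition; blocks are
#'   disjoint, contiguous, and cover all analysed units.
#' @export
four_gamete_blocks <- function(hapmat, units, cutoff = 0.05,
                               overrides = NULL, min_freq = cutoff) {
  stopifnot(cutoff > 0, cutoff < 0.5)
  poly <- vapply(units$unit, function(u)
    second_allele_freq(hapmat[, u]) >= min_freq, logical(1))
  excluded <- units$unit[!poly]
  units <- units[poly, , drop = FALSE]
  if (is.unsorted(order(units$chrom, units$pos)) &&
      any(unlist(tapply(units$pos, units$chrom, is.unsorted)))) {
    stop("units must be ordered by position within chromosome", call. = FALSE)
  }
  for (ch in unique(units$chrom)) {
    if (is.unsorted(units$pos[units$chrom == ch], strictly = TRUE)) {
      stop("units must be strictly ordered by position within chromosome",
           call. = FALSE)
    }
  }
  bin <- vapply(units$unit, function(u) {
    x <- hapmat[, u]
    tb <- sort(table(x[!is.na(x)]), decreasing = TRUE)
    out <- rep(NA_integer_, length(x))
    out[!is.na(x)] <- as.integer(x[!is.na(x)] != names(tb)[1])
    out
  }, integer(nrow(hapmat)))

  evidence <- function(i, j) {
    a <- bin[, i]; b <- bin[, j]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(FALSE)
    tb <- table(factor(a[ok], 0:1), factor(b[ok], 0:1)) / sum(ok)
    all(tb >= cutoff)
  }

  lab <- character(nrow(units))
  blk <- 0L
  for (ch in unique(units$chrom)) {
    idx <- which(units$chrom == ch)
    start <- 1L
    blk <- blk + 1L
    for (j in seq_along(idx)) {
      if (j > start && any(vapply(start:(j - 1), function(i)
        evidence(idx[i], idx[j]), logical(1)))) {
        blk <- blk + 1L
        start <- j
      }
      lab[idx[j]] <- paste0("B", blk)
    }
  }
  if (!is.null(overrides)) {
    hit <- names(overrides)[names(overrides) %in% units$unit]
    lab[match(hit, units$unit)] <- unname(overrides[hit])
  }
  # blocks = maximal contiguous runs of equal label within chromosome
  run <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)] |
                    units$chrom[-1] != units$chrom[-nrow(units)]))
  structure(data.frame(unit = units$unit, chrom = units$chrom,
                       pos = units$pos, block = paste0("blk", run),
                       label = lab, stringsAsFactors = FALSE),
            excluded = excluded)
}

#' Summarise a block partition as member runs
#'
#' @param partition result of [four_gamete_blocks()].
#' @return data.frame (block, chrom, n_units, members).
#' @export
block_summary <- function(partition) {
  sp <- split(partition, partition$block)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    block = d$block[1], chrom = d$chrom[1], n_units = nrow(d),
    members = paste(d$unit, collapse = ","), stringsAsFactors = FALSE)))
  out[order(match(out$block, unique(partition$block))), ]
}
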