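#' Call gene copy number from multiplex-PCR product patterns
#'
#' The multiplex assay amplifies products internal to the gene and a
#' product spanning the deletion breakpoints. Internal products only:
#' two copies; both product types: one copy; spanning product only: zero
#' copies. Neither product is an assay failure.
#'
#' @param internal_present logical: gene-internal PCR product(s) observed.
#' @param spanning_present logical: deletion-spanning product observed.
#' @return integer copy number(s) in {0, 1, 2}.
#' @export
call_copy_number <- function(internal_present, spanning_present) {
  stopifnot(length(internal_present) == length(spanning_present))
  if (any(!internal_present & !spanning_present)) {
    stop("no-call: neither internal nor spanning product present (assay failure)",
         call. = FALSE)
  }
  ifelse(internal_present & spanning_present, 1L,
         ifelse(internal_present, 2L, 0L))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for a biallelic site: given the allele counts,
#' enumerates all possible heterozygote counts, and sums the probabilities
#' of configurations no more probable than the observed one (two-sided by
#' probability mass; appropriate at small n).
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @return p-value in (0, 1\].
#' @export
test_hwe <- function(n_aa, n_ab, n_bb) {
  cnt <- c(n_aa, n_ab, n_bb)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(cnt)
  if (n < 1) stop("need at least one genotype", call. = FALSE)
  nA <- 2 * n_aa + n_ab
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2; nbb <- n - naa - h
    h * log(2) + lfactorial(n) - lfactorial(naa) - lfactorial(h) -
      lfactorial(nbb)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hs == n_ab)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# ---- EM haplotype phasing -------------------------------------------------

# enumerate unordered haplotype pairs compatible with one subject's
# genotype row (entries "a/b", single allele for hemizygous, NA missing).
# hemizygous rows pair the observed haplotype with "DEL".
enumerate_pairs <- function(row, copies = 2L) {
  if (!is.na(copies) && copies == 0L) {
    return(list(c("DEL", "DEL")))
  }
  if (!is.na(copies) && copies == 1L) {
    if (any(is.na(row)) || any(grepl("/", row, fixed = TRUE))) return(NULL)
    return(list(sort(c(paste(row, collapse = "|"), "DEL"))))
  }
  if (any(is.na(row))) return(NULL)
  parts <- strsplit(row, "/", fixed = TRUE)
  if (any(lengths(parts) == 1)) parts <- lapply(parts, function(p) rep(p, 2)[1:2])
  a <- vapply(parts, `[`, "", 1L); b <- vapply(parts, `[`, "", 2L)
  het <- which(a != b)
  if (length(het) == 0) {
    return(list(c(paste(a, collapse = "|"), paste(a, collapse = "|"))))
  }
  # fix the first heterozygous marker's orientation: 2^(nhet-1) pairs
  free <- het[-1]
  combos <- if (length(free) == 0) matrix(FALSE, 1, 0) else
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(free))))
  lapply(seq_len(nrow(combos)), function(k) {
    h1 <- a; h2 <- b
    flip <- free[unlist(combos[k, ])]
    tmp <- h1[flip]; h1[flip] <- h2[flip]; h2[flip] <- tmp
    sort(c(paste(h1, collapse = "|"), paste(h2, collapse = "|")))
  })
}

#' Phase haplotypes by expectation-maximisation
#'
#' Maximises the multinomial haplotype-frequency likelihood over the
#' haplotypes compatible with the observed unphased genotypes (the standard
#' EM for diplotype ambiguity), then reports each subject's
#' maximum-posterior diplotype. Subjects with one gene copy contribute a
#' single, directly observed haplotype paired with the deletion state
#' `"DEL"`; zero-copy subjects contribute two `"DEL"` chromosomes; subjects
#' with missing genotypes are excluded and reported unphased. Multiple
#' seeded restarts guard against local maxima; the log-likelihood is
#' non-decreasing within each run.
#'
#' @param geno character matrix subjects x markers; entries `"a/b"`
#'   (unordered), a single allele (hemizygous), or `NA`.
#' @param copies optional integer vector of gene copy numbers per subject
#'   (default 2 for everyone); only meaningful for CNV-capable scopes.
#' @param max_iter,tol EM stopping rule (max frequency change < `tol`).
#' @param n_restarts number of random restarts after the uniform start.
#' @param seed integer seed for restarts.
#' @param prefix haplotype name prefix passed to [name_haplotypes()].
#' @return list with `haplotypes` (data.frame haplotype/frequency/name),
#'   `phase` (data.frame subject index, hap1, hap2, posterior; NA rows for
#'   excluded subjects), `loglik`, `loglik_path`, `converged`.
#' @export
phase_em <- function(geno, copies = NULL, max_iter = 200L, tol = 1e-8,
                     n_restarts = 10L, seed = 1L, prefix = "H") {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(copies)) copies <- rep(2L, n)
  pairs <- lapply(seq_len(n), function(i) enumerate_pairs(geno[i, ], copies[i]))
  usable <- !vapply(pairs, is.null, logical(1))
  haps <- unique(unlist(pairs[usable]))
  if (length(haps) == 0) {
    return(list(haplotypes = data.frame(haplotype = character(0),
                                        frequency = numeric(0),
                                        name = character(0)),
                phase = data.frame(subject = seq_len(n), hap1 = NA, hap2 = NA,
                                   posterior = NA_real_),
                loglik = NA_real_, loglik_path = numeric(0), converged = TRUE))
  }
  # index pairs once
  idx <- lapply(pairs[usable], function(ps)
    do.call(rbind, lapply(ps, function(p) match(p, haps))))
  n_use <- sum(usable)

  run_em <- function(f0) {
    f <- f0
    path <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      counts <- numeric(length(haps))
      ll <- 0
      for (s in seq_len(n_use)) {
        pm <- idx[[s]]
        w <- f[pm[, 1]] * f[pm[, 2]] * ifelse(pm[, 1] == pm[, 2], 1, 2)
        tw <- sum(w)
        if (tw <= 0) { w <- rep(1 / length(w), length(w)); tw <- 1 }
        else w <- w / tw
        ll <- ll + log(tw)
        for (r in seq_len(nrow(pm))) {
          counts[pm[r, 1]] <- counts[pm[r, 1]] + w[r]
          counts[pm[r, 2]] <- counts[pm[r, 2]] + w[r]
        }
      }
      f_new <- counts / (2 * n_use)
      path <- c(path, ll)
      if (max(abs(f_new - f)) < tol) { f <- f_new; converged <- TRUE; break }
      f <- f_new
    }
    list(f = f, loglik = path[length(path)], path = path, converged = converged)
  }

  best <- run_em(rep(1 / length(haps), length(haps)))
  if (n_restarts > 0 && length(haps) > 1) {
    with_local_seed(seed, {
      for (r in seq_len(n_restarts)) {
        f0 <- stats::rexp(length(haps)); f0 <- f0 / sum(f0)
        cand <- run_em(f0)
        if (cand$loglik > best$loglik + 1e-12) best <- cand
      }
    })
  }
  f <- best$f
  # maximum-posterior diplotype per subject
  phase <- data.frame(subject = seq_len(n), hap1 = NA_character_,
                      hap2 = NA_character_, posterior = NA_real_,
                      stringsAsFactors = FALSE)
  ui <- which(usable)
  for (s in seq_len(n_use)) {
    pm <- idx[[s]]
    w <- f[pm[, 1]] * f[pm[, 2]] * ifelse(pm[, 1] == pm[, 2], 1, 2)
    if (sum(w) <= 0) w <- rep(1, length(w))
    w <- w / sum(w)
    k <- which.max(w)
    phase$hap1[ui[s]] <- haps[pm[k, 1]]
    phase$hap2[ui[s]] <- haps[pm[k, 2]]
    phase$posterior[ui[s]] <- w[k]
  }
  hs <- name_haplotypes(data.frame(haplotype = haps, frequency = f,
                                   stringsAsFactors = FALSE), prefix = prefix)
  list(haplotypes = hs, phase = phase, loglik = best$loglik,
       loglik_path = best$path, converged = best$converged)
}

#' Name haplotypes by descending frequency
#'
#' The most common haplotype receives the smallest number (`H1`), ties are
#' broken lexicographically by allele vector, and the whole-gene deletion
#' state keeps its distinguished name `"DEL"`.
#'
#' @param hapset data.frame with columns `haplotype` and `frequency`.
#' @param prefix name prefix (`"H"` for within-gene haplotypes, e.g.
#'   `"H-LR"` for long-range haplotypes).
#' @return the data.frame sorted by rank with a `name` column.
#' @export
name_haplotypes <- function(hapset, prefix = "H") {
  stopifnot(all(c("haplotype", "frequency") %in% names(hapset)))
  del <- hapset$haplotype == "DEL"
  rest <- hapset[!del, , drop = FALSE]
  ord <- order(-rest$frequency, rest$haplotype)
  rest <- rest[ord, , drop = FALSE]
  rest$name <- paste0(prefix, seq_len(nrow(rest)))
  out <- rest
  if (any(del)) {
    d <- hapset[del, , drop = FALSE]
    d$name <- "DEL"
    out <- rbind(out, d)
  }
  rownames(out) <- NULL
  out
}

#' Reconstruct unphased genotypes from a haplotype pair
#'
#' Inverse of phasing: rebuilds the unordered genotype entries implied by
#' two haplotype strings (markers joined by `"|"`). A `"DEL"` haplotype
#' contributes no alleles: one deletion gives hemizygous single-allele
#' entries, two give `NA`.
#'
#' @param hap1,hap2 haplotype strings.
#' @return character vector of genotype entries.
#' @export
unphase_pair <- function(hap1, hap2) {
  if (hap1 == "DEL" && hap2 == "DEL") return(NA_character_)
  if (hap1 == "DEL" || hap2 == "DEL") {
    return(strsplit(if (hap1 == "DEL") hap2 else hap1, "|", fixed = TRUE)[[1]])
  }
  a <- strsplit(hap1, "|", fixed = TRUE)[[1]]
  b <- strsplit(hap2, "|", fixed = TRUE)[[1]]
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

#' Haplotype switch error between true and inferred phase
#'
#' For each subject, orients the inferred diplotype against the truth at
#' the first heterozygous marker and counts orientation switches along the
#' remaining heterozygous markers; the rate is total switches over total
#' switch opportunities (heterozygous markers minus one, summed).
#'
#' @param true1,true2,est1,est2 character vectors of haplotype strings
#'   (markers joined by `"|"`), one element per subject.
#' @return switch error rate in \[0, 1\] (NaN if no opportunities).
#' @export
switch_error_rate <- function(true1, true2, est1, est2) {
  stopifnot(length(true1) == length(true2), length(est1) == length(true1))
  sw <- 0L; opp <- 0L
  for (i in seq_along(true1)) {
    if (any(is.na(c(true1[i], true2[i], est1[i], est2[i])))) next
    t1 <- strsplit(true1[i], "|", fixed = TRUE)[[1]]
    t2 <- strsplit(true2[i], "|", fixed = TRUE)[[1]]
    e1 <- strsplit(est1[i], "|", fixed = TRUE)[[1]]
    het <- which(t1 != t2)
    if (length(het) < 2) next
    o <- ifelse(e1[het] == t1[het], 0L, 1L)
    sw <- sw + sum(abs(diff(o)))
    opp <- opp + length(het) - 1L
  }
  if (opp == 0) return(NaN)
  sw / opp
}
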