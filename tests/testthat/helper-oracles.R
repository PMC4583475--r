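# Independent oracles used across the suite. Each reimplements the target
# quantity by brute force (enumeration, grid search) with no shared code
# with the package internals it checks.

# exact HWE p by direct enumeration of heterozygote counts with fixed
# allele counts, probabilities from first-principles multinomial ratios
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  probs <- c()
  hs <- c()
  for (h in 0:min(nA, 2 * n - nA)) {
    if ((nA - h) %% 2 != 0) next
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    if (nbb < 0) next
    hs <- c(hs, h)
    probs <- c(probs, exp(lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) -
                            lgamma(nbb + 1) + h * log(2)))
  }
  probs <- probs / sum(probs)
  obs <- probs[hs == n_ab]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# two-site haplotype frequency likelihood maximised by grid search over
# the 4-haplotype simplex (haplotypes ordered ref/alt x ref/alt); gives a
# lower bound on the attainable maximum at resolution `step`
oracle_em_2site <- function(geno_rows, step = 0.02) {
  pairs_of <- function(gt) {
    p <- strsplit(strsplit(gt, "|", fixed = TRUE)[[1]], "/", fixed = TRUE)
    a <- c(p[[1]][1], p[[2]][1]); b <- c(p[[1]][2], p[[2]][2])
    het <- which(a != b)
    if (length(het) <= 1) {
      list(c(paste(a, collapse = ""), paste(b, collapse = "")))
    } else {
      list(c(paste(a, collapse = ""), paste(b, collapse = "")),
           c(paste(c(a[1], b[2]), collapse = ""),
             paste(c(b[1], a[2]), collapse = "")))
    }
  }
  plist <- lapply(geno_rows, pairs_of)
  haps <- sort(unique(unlist(plist)))
  stopifnot(length(haps) <= 4)
  while (length(haps) < 4) haps <- c(haps, paste0(".pad", length(haps)))
  grid <- expand.grid(f1 = seq(0, 1, step), f2 = seq(0, 1, step),
                      f3 = seq(0, 1, step))
  grid <- grid[rowSums(grid) <= 1 + 1e-12, ]
  G <- cbind(grid$f1, grid$f2, grid$f3, pmax(0, 1 - rowSums(grid)))
  colnames(G) <- haps
  # aggregate identical genotype patterns
  keys <- vapply(plist, function(ps) paste(vapply(ps, paste, "", collapse = ","),
                                           collapse = ";"), "")
  ll <- 0
  for (key in unique(keys)) {
    ps <- plist[[match(key, keys)]]
    cnt <- sum(keys == key)
    lik <- rowSums(vapply(ps, function(p)
      (if (p[1] == p[2]) 1 else 2) * G[, p[1]] * G[, p[2]],
      numeric(nrow(G))))
    ll <- ll + cnt * log(pmax(lik, 1e-300))
  }
  best <- which.max(ll)
  list(loglik = ll[best], freq = setNames(G[best, ], haps))
}

# four-gamete recombination evidence by explicit gamete-string tabulation
oracle_evidence <- function(h1, h2, cutoff = 0.05) {
  ok <- !is.na(h1) & !is.na(h2)
  g <- table(paste(h1[ok], h2[ok]))
  length(g) == 4 && all(g / sum(g) >= cutoff)
}

# minimum number of contiguous blocks with no within-block evidence, by DP
oracle_min_blocks <- function(bin, cutoff = 0.05) {
  m <- ncol(bin)
  ev <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ev[i, j] <- ev[j, i] <- oracle_evidence(bin[, i], bin[, j], cutoff)
  }
  valid <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    valid[i, j] <- !any(ev[i:j, i:j])
  }
  dp <- rep(Inf, m + 1); dp[1] <- 0
  for (j in seq_len(m)) {
    for (i in seq_len(j)) {
      if (valid[i, j]) dp[j + 1] <- min(dp[j + 1], dp[i] + 1)
    }
  }
  list(min_blocks = dp[m + 1], evidence = ev)
}

# psychometric MLE by dense grid search over (mu, slope)
oracle_psy_grid <- function(lc, resp, guess, mu_grid, slope_grid) {
  best <- list(nll = Inf)
  for (mu in mu_grid) for (s in slope_grid) {
    p <- guess + (1 - guess) * plogis(s * (lc - mu))
    p <- pmin(1 - 1e-9, pmax(1e-9, p))
    nll <- -sum(resp * log(p) + (1 - resp) * log(1 - p))
    if (nll < best$nll) best <- list(nll = nll, mu = mu, slope = s)
  }
  best
}

# Hill least squares by dense grid search over (A, log10 EC50, n)
oracle_hill_grid <- function(conc, y, a_grid, l50_grid, n_grid) {
  best <- list(rss = Inf)
  lc <- log10(conc)
  for (a in a_grid) for (l in l50_grid) for (nn in n_grid) {
    pred <- a / (1 + 10^(nn * (l - lc)))
    rss <- sum((y - pred)^2)
    if (rss < best$rss) best <- list(rss = rss, a = a, l50 = l, n = nn)
  }
  best
}

# tiny single-block scenario with an optional whole-gene deletion haplotype
mini_del_scenario <- function(freq_del = 1) {
  genes <- data.frame(gene = "GENED", chrom = "chr1", block = "D",
                      pos = 1e6, cnv = TRUE, stringsAsFactors = FALSE)
  sites <- data.frame(site_id = "GENED_s1", gene = "GENED", chrom = "chr1",
                      pos = 1e6 + 150, ref = "A", alt = "G",
                      consequence = "missense", stringsAsFactors = FALSE)
  gene_haps <- list(GENED = list(H1 = "A"))
  comp <- list(LRH1 = c(GENED = "DEL"), LRH2 = c(GENED = "H1"))
  lrh_pool <- list(D = list(freq = c(LRH1 = freq_del, LRH2 = 1 - freq_del),
                            comp = comp))
  receptor_table <- data.frame(compound = "x", gene = "GENED", allele = "H1",
                               activation_threshold = 1e-6, ec50 = 1e-5,
                               amplitude = 0.5, hill_n = 1,
                               stringsAsFactors = FALSE)
  link <- data.frame(compound = "x", offset = 0, slope = 1,
                     subject_sd = 0.1, stringsAsFactors = FALSE)
  psych <- data.frame(compound = "x", start = 1e-7, ratio = 1.5,
                      n_steps = 12L, n_reps = 3L, guess = 0.25,
                      det_shift = 0.15, slope_det = 8, slope_rec = 8,
                      int_shift = 0.45, int_slope = 0.35, imax_mean = 80,
                      imax_sd = 8, int_noise_sd = 4, stringsAsFactors = FALSE)
  plate <- list(conc = 10^seq(-9, -4, 0.5), n_days = 6L, n_pc_wells = 3L,
                day_sd = 0.1, noise_sd = 0.003, f0_mean = 1000, f0_sd = 100,
                artefact_amp = 0.05, pc_response = 1,
                ceiling = c(x = 1e-4))
  scenario(genes, sites, gene_haps, lrh_pool, receptor_table, link,
           psych, plate)
}
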