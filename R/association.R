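#' Scan configuration
#'
#' @param freq_filter minimum genotype-class sample frequency (classes at
#'   or below it are dropped, their subjects excluded for that unit).
#' @param alpha nominal significance level.
#' @param n_perm permutations for the experiment-wide threshold (>= 1000).
#' @param seed integer seed.
#' @param drop_outliers exclude Peirce-flagged phenotype cells.
#' @param use_censored include boundary-clamped censored cells.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(freq_filter = 0.05, alpha = 0.05, n_perm = 1000L,
                        seed = 1L, drop_outliers = TRUE,
                        use_censored = TRUE) {
  stopifnot(freq_filter > 0, freq_filter < 0.5, n_perm >= 1)
  structure(list(freq_filter = freq_filter, alpha = alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 drop_outliers = drop_outliers, use_censored = use_censored),
            class = "scan_config")
}

#' Genotype-phenotype linear mixed model for one unit
#'
#' Fits `log10(y)_ij = mu + beta_g(i) + u_i + e_ij` with a subject random
#' intercept by REML (nlme) and tests the genotype fixed effect by an F
#' test with containment denominator degrees of freedom. For balanced
#' replicate designs this equals the one-way ANOVA on subject means. If the
#' mixed model cannot be estimated (e.g. zero residual variance), the
#' subject-means ANOVA is used directly and the result flagged.
#'
#' @param y response (log10 concentration), one element per observation.
#' @param genotype genotype class per observation (factor or character).
#' @param subject subject id per observation.
#' @return list: `p`, `f`, `df`, `class_means` (of subject means, log10),
#'   `class_n` (subjects per class), `n_classes`, `method`, `degenerate`.
#' @export
fit_lmm <- function(y, genotype, subject) {
  d <- data.frame(y = y, genotype = factor(genotype),
                  subject = factor(subject))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$genotype <- droplevels(d$genotype)
  d$subject <- droplevels(d$subject)
  sm <- tapply(d$y, d$subject, mean)
  sg <- tapply(as.character(d$genotype), d$subject, `[`, 1)
  k <- nlevels(d$genotype)
  means <- tapply(sm, sg, mean)
  cls_n <- table(sg)
  base <- list(p = 1, f = NA_real_, df = c(NA, NA), class_means = means,
               class_n = cls_n, n_classes = k, method = "none",
               degenerate = TRUE)
  if (k < 2 || length(sm) <= k) return(base)
  if (stats::var(d$y) == 0) return(base)
  res <- tryCatch({
    fit <- nlme::lme(y ~ genotype, random = ~ 1 | subject, data = d,
                     method = "REML")
    a <- stats::anova(fit)
    list(p = a["genotype", "p-value"], f = a["genotype", "F-value"],
         df = c(a["genotype", "numDF"], a["genotype", "denDF"]),
         class_means = means, class_n = cls_n, n_classes = k,
         method = "lmm", degenerate = FALSE)
  }, error = function(e) NULL)
  if (is.null(res)) {
    # fall back to the subject-means one-way ANOVA (equivalent under balance)
    f <- subject_means_f(sm, sg)
    res <- list(p = f$p, f = f$f, df = f$df, class_means = means,
                class_n = cls_n, n_classes = k, method = "subject_means",
                degenerate = is.na(f$p))
    if (is.na(res$p)) res$p <- 1
  }
  res
}

# one-way ANOVA on subject means
subject_means_f <- function(sm, sg) {
  g <- factor(sg)
  k <- nlevels(g); n <- length(sm)
  if (k < 2 || n <= k) return(list(p = NA_real_, f = NA_real_, df = c(NA, NA)))
  gm <- tapply(sm, g, mean); ng <- tabulate(g)
  ssb <- sum(ng * (gm - mean(sm))^2)
  ssw <- sum((sm - gm[g])^2)
  if (ssw <= 0) return(list(p = NA_real_, f = Inf, df = c(k - 1, n - k)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(p = stats::pf(f, k - 1, n - k, lower.tail = FALSE), f = f,
       df = c(k - 1, n - k))
}

#' Genotype units of a cohort
#'
#' Builds the per-subject categorical genotype classes scanned at each
#' level: unordered allele pairs at SNPs, gene haplotype diplotypes, or
#' long-range haplotype diplotypes (true phase of a synthetic cohort; use
#' [units_from_matrix()] for inferred phase).
#'
#' @param cohort a `tas2r_cohort`.
#' @param level `"snp"`, `"gene"` or `"block"`.
#' @return named list unit -> named character vector subject -> class.
#' @export
genotype_units <- function(cohort, level = c("snp", "gene", "block")) {
  level <- match.arg(level)
  subjects <- cohort$subjects
  if (level == "snp") {
    gm <- genotype_matrix(cohort)
    return(lapply(stats::setNames(colnames(gm), colnames(gm)),
                  function(s) stats::setNames(gm[, s], subjects)))
  }
  src <- if (level == "gene") cohort$gene_hap else cohort$lrh
  lapply(stats::setNames(names(src), names(src)), function(u) {
    m <- src[[u]]
    stats::setNames(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]),
                          sep = "/"), subjects)
  })
}

#' Genotype units from a subjects-by-units class matrix
#'
#' @param m character matrix (rownames = subjects) of genotype classes,
#'   e.g. [gene_diplotype_matrix()] output.
#' @return named list unit -> named character vector subject -> class.
#' @export
units_from_matrix <- function(m) {
  stopifnot(!is.null(rownames(m)))
  lapply(stats::setNames(colnames(m), colnames(m)),
         function(u) stats::setNames(m[, u], rownames(m)))
}

# apply the class frequency filter to one unit; returns NULL if < 2 classes
filter_unit <- function(classes, freq_filter) {
  classes <- classes[!is.na(classes)]
  tb <- table(classes) / length(classes)
  keep <- names(tb)[tb > freq_filter]
  classes <- classes[classes %in% keep]
  if (length(unique(classes)) < 2) return(NULL)
  classes
}

#' Genotype-phenotype association scan
#'
#' One mixed-model test per unit passing the class-frequency filter, per
#' compound and phenotype measure. Subjects in dropped (rare) classes are
#' excluded for that unit. Experiment-wide significance is assessed against
#' a permutation min-p threshold computed per compound x measure over the
#' supplied units (see [experimentwide_threshold()]).
#'
#' @param pheno phenotype table from [phenotype_table()] (or any data.frame
#'   with subject, compound, measure, conc and optional repetition,
#'   censor, outlier columns).
#' @param units genotype units ([genotype_units()] / [units_from_matrix()]).
#' @param config a [scan_config()].
#' @param level label stored on the results (`"snp"`, `"gene"`, `"block"`).
#' @param experimentwide compute the permutation threshold and flag results.
#' @return data.frame of association results, one row per unit x compound x
#'   measure, with `p`, class summaries and significance flags; the
#'   per-(compound, measure) thresholds are in attribute `alpha_star`.
#' @export
scan_associations <- function(pheno, units, config = scan_config(),
                              level = "snp", experimentwide = TRUE) {
  if (!is.null(pheno$outlier) && config$drop_outliers) {
    pheno <- pheno[!pheno$outlier, , drop = FALSE]
  }
  if (!config$use_censored && !is.null(pheno$censor)) {
    pheno <- pheno[pheno$censor == "none", , drop = FALSE]
  }
  pheno <- pheno[!is.na(pheno$conc), , drop = FALSE]
  if (length(intersect(pheno$subject, names(units[[1]]))) == 0) {
    stop("no subjects shared between phenotype and genotype data",
         call. = FALSE)
  }
  out <- list(); k <- 0L
  thresholds <- list()
  for (cm in unique(pheno$compound)) {
    for (ms in unique(pheno$measure)) {
      d <- pheno[pheno$compound == cm & pheno$measure == ms, , drop = FALSE]
      if (nrow(d) == 0) next
      a_star <- NA_real_
      if (experimentwide) {
        a_star <- experimentwide_threshold(d, units, config)$alpha_star
      }
      thresholds[[paste(cm, ms, sep = ".")]] <- a_star
      for (u in names(units)) {
        cl <- filter_unit(units[[u]], config$freq_filter)
        if (is.null(cl)) next
        di <- d[d$subject %in% names(cl), , drop = FALSE]
        if (nrow(di) == 0) next
        fit <- fit_lmm(log10(di$conc), cl[di$subject], di$subject)
        if (fit$n_classes < 2) next
        k <- k + 1L
        out[[k]] <- data.frame(
          level = level, unit = u, compound = cm, measure = ms,
          n_classes = fit$n_classes, p = fit$p, f = fit$f,
          degenerate = fit$degenerate,
          significant_at_alpha = !is.na(fit$p) && fit$p <= config$alpha,
          significant_experimentwide = !is.na(a_star) && !is.na(fit$p) &&
            fit$p <= a_star,
          class_means = paste(sprintf("%s=%.3f", names(fit$class_means),
                                      fit$class_means), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (k > 0) do.call(rbind, out) else
    data.frame(level = character(0), unit = character(0))
  attr(res, "alpha_star") <- unlist(thresholds)
  res
}

#' Experiment-wide significance threshold by min-p permutation
#'
#' Permutes subject phenotype vectors as units (preserving the LD among
#' units and the within-subject replication structure), recomputes for each
#' permutation the minimum association p-value across all units, and
#' returns the `alpha` quantile of that null min-p distribution — the
#' per-test threshold that keeps the experiment-wide error at `alpha`
#' under the observed LD. The permutation statistic is the one-way F on
#' subject means, the balanced-design equivalent of the mixed-model F.
#'
#' @param pheno phenotype rows for a single compound x measure.
#' @param units genotype units as in [scan_associations()].
#' @param config a [scan_config()] (`n_perm`, `alpha`, `seed`,
#'   `freq_filter`).
#' @return list: `alpha_star`, `min_p` (the permutation distribution),
#'   `n_units`.
#' @export
experimentwide_threshold <- function(pheno, units, config = scan_config()) {
  if (config$n_perm < 1000) stop("need n_perm >= 1000", call. = FALSE)
  pheno <- pheno[!is.na(pheno$conc), , drop = FALSE]
  sm <- tapply(log10(pheno$conc), pheno$subject, mean)
  subjects <- names(sm)
  n <- length(subjects)
  # prepare per-unit group indicators over the subject subset
  prep <- list()
  for (u in names(units)) {
    cl <- filter_unit(units[[u]][subjects], config$freq_filter)
    if (is.null(cl)) next
    su <- match(names(cl), subjects)
    g <- factor(cl)
    if (nlevels(g) < 2 || length(su) <= nlevels(g)) next
    G <- stats::model.matrix(~ g - 1)
    prep[[u]] <- list(su = su, G = G, k = nlevels(g), ng = colSums(G))
  }
  if (length(prep) == 0) stop("no testable units after filtering", call. = FALSE)
  B <- config$n_perm
  Y <- with_local_seed(config$seed, {
    vapply(seq_len(B), function(b) sm[sample.int(n)], numeric(n))
  })
  min_p <- rep(1, B)
  for (pr in prep) {
    Ys <- Y[pr$su, , drop = FALSE]
    tot <- colSums(Ys); ss <- colSums(Ys^2)
    m <- length(pr$su)
    sums <- crossprod(pr$G, Ys)                       # k x B
    ssb <- colSums(sums^2 / pr$ng) - tot^2 / m
    sst <- ss - tot^2 / m
    ssw <- pmax(sst - ssb, 0)
    f <- (ssb / (pr$k - 1)) / (ssw / (m - pr$k))
    p <- stats::pf(f, pr$k - 1, m - pr$k, lower.tail = FALSE)
    p[!is.finite(p)] <- 0
    min_p <- pmin(min_p, p)
  }
  list(alpha_star = unname(stats::quantile(min_p, config$alpha)),
       min_p = min_p, n_units = length(prep))
}

#' Sidak-style threshold for a given number of effective tests
#'
#' Fast closed-form alternative to the permutation threshold:
#' `1 - (1 - alpha)^(1/m_eff)`.
#'
#' @param m_eff effective number of independent tests.
#' @param alpha experiment-wide level.
#' @return per-test threshold.
#' @export
sidak_threshold <- function(m_eff, alpha = 0.05) {
  stopifnot(m_eff >= 1)
  1 - (1 - alpha)^(1 / m_eff)
}

#' Bonferroni-adjusted decisions
#'
#' Used at gene-specific and LD-block level: reject iff `p <= alpha / m`.
#'
#' @param p p-values.
#' @param m number of tests (default `length(p)`).
#' @param alpha family-wise level.
#' @return data.frame (p, p_adj, reject).
#' @export
bonferroni <- function(p, m = length(p), alpha = 0.05) {
  stopifnot(m >= 1)
  data.frame(p = p, p_adj = pmin(1, p * m), reject = p <= alpha / m)
}
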