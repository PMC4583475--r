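#' Baseline-normalised fluorescence change
#'
#' `(F - F0) / F0`: peak height minus background, divided by background.
#'
#' @param f peak fluorescence (RFU).
#' @param f0 background fluorescence (RFU), > 0.
#' @return delta-F/F ratio(s).
#' @export
delta_f_over_f <- function(f, f0) {
  if (any(!is.finite(f0)) || any(f0 <= 0)) {
    stop("background fluorescence F0 must be > 0", call. = FALSE)
  }
  (f - f0) / f0
}

#' Three-step fluorescence correction
#'
#' Applies the plate corrections in fixed order: (1) well-to-well — each
#' well's response is expressed relative to its own baseline as delta-F/F;
#' (2) negative control — the matched empty-vector mean response per
#' (day, compound, concentration) is subtracted, removing
#' receptor-independent artefacts and drift (empty-vector wells therefore
#' have mean 0 by construction); (3) positive control — responses are
#' rescaled by grand-mean/day-mean of the positive-control response to
#' align experimental days. The whole pipeline is invariant to detector
#' gain (any common rescaling of F and F0).
#'
#' @param plates plate table as from [simulate_plates()] (columns day,
#'   construct, compound, conc, F, F0).
#' @return the table with a `corrected` column (delta-F/F); wells without a
#'   matched negative control are dropped (attribute `dropped_wells`),
#'   days with non-positive control means are dropped (attribute
#'   `dropped_days`).
#' @export
correct_fluorescence <- function(plates) {
  p <- plates
  p$dff <- delta_f_over_f(p$F, p$F0)
  pc <- p$construct == "positive_control"
  if (!any(pc)) stop("no positive-control wells", call. = FALSE)
  day_mean <- tapply(p$dff[pc], p$day[pc], mean)
  bad_days <- names(day_mean)[day_mean <= 0]
  grand <- mean(p$dff[pc & !(p$day %in% bad_days)])
  p <- p[!(p$day %in% bad_days), , drop = FALSE]
  ev <- p$construct == "empty_vector"
  key <- paste(p$day, p$compound, signif(p$conc, 8), sep = "\r")
  neg_mean <- tapply(p$dff[ev], key[ev], mean)
  p$corrected <- NA_real_
  exp_rows <- !(p$construct %in% "positive_control")
  matched <- key %in% names(neg_mean)
  use <- exp_rows & matched
  scale <- grand / day_mean[as.character(p$day)]
  p$corrected[use] <- (p$dff[use] - neg_mean[key[use]]) * scale[use]
  dropped <- p$well[exp_rows & !matched]
  p <- p[!(exp_rows & !matched), , drop = FALSE]
  structure(p, dropped_wells = dropped, dropped_days = bad_days)
}

#' Activation threshold call for one receptor construct
#'
#' One-way ANOVA across the concentration groups plus the empty-vector
#' control on corrected delta-F/F, followed by per-concentration
#' comparisons against the matched empty-vector wells with Bonferroni
#' correction (m = number of tested concentrations). The threshold is the
#' lowest concentration with a significant positive response; `NA` when no
#' concentration is significant up to the compound's artefact-free ceiling.
#'
#' @param construct_resp data.frame with columns `conc` and `corrected`
#'   for the construct's wells.
#' @param control_resp same for the matched empty-vector wells.
#' @param alpha family-wise level.
#' @param ceiling highest artefact-free concentration (higher
#'   concentrations are excluded).
#' @return list: `threshold` (M or NA), `anova_p`, `tests` (per-conc
#'   data.frame).
#' @export
call_threshold <- function(construct_resp, control_resp, alpha = 0.05,
                           ceiling = Inf) {
  cr <- construct_resp[construct_resp$conc <= ceiling, , drop = FALSE]
  ct <- control_resp[control_resp$conc <= ceiling, , drop = FALSE]
  concs <- sort(unique(cr$conc))
  if (length(concs) < 2 || min(table(cr$conc)) < 3) {
    stop("need >= 2 concentrations with >= 3 replicates each", call. = FALSE)
  }
  y <- c(cr$corrected, ct$corrected)
  grp <- factor(c(paste0("c", match(cr$conc, concs)), rep("control", nrow(ct))))
  an_p <- if (stats::var(y) == 0) 1 else
    stats::anova(stats::lm(y ~ grp))[["Pr(>F)"]][1]
  m <- length(concs)
  tests <- data.frame(conc = concs, p = NA_real_, mean_diff = NA_real_)
  for (i in seq_along(concs)) {
    a <- cr$corrected[cr$conc == concs[i]]
    b <- ct$corrected[ct$conc == concs[i]]
    if (length(b) < 2) b <- ct$corrected
    tests$mean_diff[i] <- mean(a) - mean(b)
    tests$p[i] <- if (stats::sd(c(a, b)) == 0) 1 else
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  }
  tests$significant <- !is.na(tests$p) & tests$p <= alpha / m &
    tests$mean_diff > 0
  thr <- NA_real_
  if (!is.na(an_p) && an_p <= alpha && any(tests$significant)) {
    thr <- min(tests$conc[tests$significant])
  }
  list(threshold = thr, anova_p = an_p, tests = tests)
}

#' Hill dose-response fit
#'
#' Nonlinear least squares fit of `f(c) = A * c^n / (EC50^n + c^n)` to
#' mean corrected responses, with EC50 bounded to one decade beyond the
#' tested range, Hill coefficient in \[0.5, 4\] and amplitude >= 0;
#' multiple deterministic starts, best residual sum of squares wins.
#' Boundary-pinned or non-convergent fits are marked not activated.
#'
#' @param conc concentrations (M), >= 4 values.
#' @param response mean corrected delta-F/F per concentration.
#' @return list of class `hill_fit`: `ec50`, `amplitude`, `hill_n`, `rss`,
#'   `converged`, `activated`.
#' @export
fit_hill <- function(conc, response) {
  ok <- is.finite(conc) & is.finite(response)
  conc <- conc[ok]; response <- response[ok]
  if (length(conc) < 4) stop("need >= 4 concentrations", call. = FALSE)
  lc <- log10(conc)
  lo <- min(lc) - 1; hi <- max(lc) + 1
  d <- data.frame(lc = lc, y = response)
  best <- NULL
  for (l0 in stats::quantile(lc, c(.25, .5, .75))) {
    for (a0 in c(max(response), max(response) * 0.6)) {
      fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
        y ~ a / (1 + 10^(n * (l50 - lc))), data = d,
        start = list(a = max(a0, 1e-3), l50 = unname(l0), n = 1),
        lower = c(0, lo, 0.5), upper = c(Inf, hi, 4),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        cf <- stats::coef(fit)
        best <- list(ec50 = 10^unname(cf["l50"]), amplitude = unname(cf["a"]),
                     hill_n = unname(cf["n"]), rss = rss,
                     converged = fit$convInfo$isConv %||% TRUE)
      }
    }
  }
  if (is.null(best)) {
    best <- list(ec50 = NA_real_, amplitude = NA_real_, hill_n = NA_real_,
                 rss = NA_real_, converged = FALSE)
  }
  l50 <- if (is.na(best$ec50)) NA else log10(best$ec50)
  pinned <- !is.na(l50) && (l50 <= lo + 1e-6 || l50 >= hi - 1e-6)
  best$activated <- isTRUE(best$converged) && !pinned &&
    !is.na(best$amplitude) && best$amplitude > 0.02
  class(best) <- "hill_fit"
  best
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: EC50 %.3g M, amplitude %.3f dF/F, n %.2f%s\n",
              x$ec50, x$amplitude, x$hill_n,
              if (x$activated) "" else " (not activated)"))
  invisible(x)
}

#' Dose-response table for all constructs of corrected plates
#'
#' Per (construct, compound): calls the activation threshold against the
#' matched empty vector and fits the Hill model to the mean corrected
#' responses (concentrations above the compound's artefact-free ceiling
#' excluded).
#'
#' @param corrected output of [correct_fluorescence()].
#' @param ceiling named numeric, artefact-free ceiling per compound
#'   (defaults to no ceiling).
#' @param alpha level for the threshold call.
#' @return data.frame (gene, allele, construct, compound, threshold_conc,
#'   ec50, amplitude, hill_n, activated, anova_p).
#' @export
dose_response_table <- function(corrected, ceiling = NULL, alpha = 0.05) {
  p <- corrected
  out <- list(); k <- 0L
  for (cm in unique(stats::na.omit(p$compound))) {
    ci <- p[!is.na(p$compound) & p$compound == cm, , drop = FALSE]
    ceil <- if (!is.null(ceiling) && cm %in% names(ceiling)) ceiling[[cm]] else Inf
    ctrl <- ci[ci$construct == "empty_vector", , drop = FALSE]
    for (cs in setdiff(unique(ci$construct), c("empty_vector", "positive_control"))) {
      d <- ci[ci$construct == cs, , drop = FALSE]
      thr <- call_threshold(d[, c("conc", "corrected")],
                            ctrl[, c("conc", "corrected")],
                            alpha = alpha, ceiling = ceil)
      du <- d[d$conc <= ceil, , drop = FALSE]
      mm <- tapply(du$corrected, du$conc, mean)
      hf <- fit_hill(as.numeric(names(mm)), as.numeric(mm))
      k <- k + 1L
      out[[k]] <- data.frame(
        gene = d$gene[1], allele = d$allele[1], construct = cs,
        compound = cm, threshold_conc = thr$threshold,
        ec50 = if (hf$activated) hf$ec50 else NA_real_,
        amplitude = if (hf$activated) hf$amplitude else 0,
        hill_n = if (hf$activated) hf$hill_n else NA_real_,
        activated = hf$activated && !is.na(thr$threshold),
        anova_p = thr$anova_p, rss = hf$rss, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
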