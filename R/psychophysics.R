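#' Geometric concentration series
#'
#' `c_k = start * ratio^(k-1)`, the ascending series used in the 4-AFC
#' procedure (twelve steps with a 1.5 common ratio in the default design).
#'
#' @param start first concentration (M), > 0.
#' @param ratio common ratio, > 0.
#' @param n_steps number of steps, >= 1.
#' @return numeric vector of concentrations.
#' @export
geometric_series <- function(start, ratio, n_steps) {
  stop_if_not_positive(start, "start")
  stop_if_not_positive(ratio, "ratio")
  if (n_steps < 1 || n_steps != round(n_steps)) {
    stop("`n_steps` must be a positive integer", call. = FALSE)
  }
  start * ratio^(seq_len(n_steps) - 1)
}

#' Fit a psychometric function by maximum likelihood
#'
#' Fits `P(response) = gamma + (1 - gamma) * logistic(slope * (log10 c -
#' mu))` to binary responses over a concentration series, by Bernoulli
#' maximum likelihood from five deterministic starting points (ties broken
#' by likelihood, then smallest slope). The guess rate gamma is 0.25 for
#' 4-AFC detection and 0 for yes/no recognition; the reported threshold
#' `10^mu` is the midpoint of the non-guessing component (P = 0.625 for
#' detection, 0.5 for recognition). Degenerate series (all success /
#' at-chance everywhere) yield censored fits at the series boundary rather
#' than errors.
#'
#' @param conc concentrations (M).
#' @param resp binary responses (0/1; NA dropped).
#' @param kind `"detection"` (gamma = 0.25) or `"recognition"` (gamma = 0).
#' @param guess optional explicit guess rate overriding `kind`.
#' @return list of class `psychometric_fit`: `mu` (log10 M), `slope`
#'   (1/log10-unit, > 0), `threshold` (M), `guess`, `censor` (`"none"`,
#'   `"low"`, `"high"`), `converged`, `loglik`, `n`.
#' @export
fit_psychometric <- function(conc, resp, kind = c("detection", "recognition"),
                             guess = NULL) {
  kind <- match.arg(kind)
  g <- guess %||% if (kind == "detection") 0.25 else 0
  ok <- !is.na(resp) & !is.na(conc)
  conc <- conc[ok]; resp <- resp[ok]
  if (length(unique(conc)) < 4) {
    stop("need responses at >= 4 concentration steps", call. = FALSE)
  }
  lc <- log10(conc)
  lo <- min(lc); hi <- max(lc)
  out <- list(mu = NA_real_, slope = NA_real_, threshold = NA_real_,
              guess = g, censor = "none", converged = TRUE,
              loglik = NA_real_, n = length(resp), kind = kind)
  class(out) <- "psychometric_fit"

  if (all(resp == 1)) {            # success even at the lowest step
    out$mu <- lo; out$threshold <- 10^lo; out$censor <- "low"
    out$slope <- Inf
    return(out)
  }
  # at or below the guess rate everywhere -> threshold above tested range
  ph <- vapply(split(resp, lc), mean, numeric(1))
  if (all(resp == 0) ||
      (stats::binom.test(sum(resp), length(resp),
                         p = min(g + 0.02, 0.999),
                         alternative = "greater")$p.value > 0.5 &&
       mean(resp) <= g + 0.05)) {
    out$mu <- hi; out$threshold <- 10^hi; out$censor <- "high"
    out$slope <- Inf
    return(out)
  }

  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    p <- g + (1 - g) * stats::plogis(s * (lc - mu))
    p <- pmin(1 - 1e-9, pmax(1e-9, p))
    -sum(resp * log(p) + (1 - resp) * log(1 - p))
  }
  starts <- lapply(stats::quantile(c(lo, hi), c(.15, .3, .5, .7, .85)),
                   function(m) c(m, log(4)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = c(lo - 3, log(0.5)), upper = c(hi + 3, log(50))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[2] < best$par[2])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    out$converged <- FALSE
    return(out)
  }
  out$mu <- best$par[1]
  out$slope <- exp(best$par[2])
  out$threshold <- 10^out$mu
  out$loglik <- -best$value
  out$converged <- best$convergence == 0
  if (out$mu < lo) out$censor <- "low"
  if (out$mu > hi) out$censor <- "high"
  out
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("psychometric fit (%s): threshold %.3g M, slope %.2f, censor %s\n",
              x$kind, x$threshold, x$slope, x$censor))
  invisible(x)
}

# Gould's computation of Peirce's criterion: squared threshold error ratio
# for N observations, k doubtful, m unknown quantities.
peirce_x2 <- function(N, k, m = 1) {
  if (N - m - k <= 0) return(NA_real_)
  Q <- (k^k * (N - k)^(N - k) / N^N)^(1 / N)
  r_new <- 1; r_old <- 0
  x2 <- 0
  while (abs(r_new - r_old) > N * 2e-16) {
    ldiv <- if (r_new^k == 0) 1e-10 else r_new^k
    x2 <- 1 + (N - m - k) / k * (1 - ((Q^N) / ldiv)^(2 / (N - m - k)))
    if (x2 < 0) {
      x2 <- 0; r_new <- r_old
    } else {
      r_old <- r_new
      # R = exp((x2-1)/2) * erfc(sqrt(x2)/sqrt(2))
      r_new <- exp((x2 - 1) / 2) *
        2 * stats::pnorm(sqrt(x2), lower.tail = FALSE)
    }
  }
  x2
}

#' Outlier rejection by Peirce's criterion
#'
#' Gould's iterative algorithm for one unknown quantity: starting from one
#' doubtful observation, computes the criterion's maximum allowable
#' deviation `sqrt(x2) * sd`, rejects observations exceeding it (deviations
#' taken from the full-sample mean and standard deviation), and increases
#' the allowed number of doubtful observations while more are rejected.
#' Idempotent on its own output by construction of the fixed point.
#'
#' @param values numeric vector (n >= 3 finite values required; otherwise a
#'   warning and no rejection).
#' @return logical vector, `TRUE` = keep, `FALSE` = reject.
#' @export
peirce_outliers <- function(values) {
  keep <- rep(TRUE, length(values))
  fin <- is.finite(values)
  if (sum(fin) < 3) {
    warning("fewer than 3 finite values: Peirce's criterion not applied")
    return(keep)
  }
  x <- values[fin]
  N <- length(x)
  mu <- mean(x); sdev <- stats::sd(x)
  if (sdev == 0) return(keep)
  dev <- abs(x - mu)
  k <- 1L
  rejected <- 0L
  repeat {
    x2 <- peirce_x2(N, k)
    if (is.na(x2)) break
    thr <- sqrt(x2) * sdev
    n_rej <- sum(dev > thr)
    if (n_rej == 0 || n_rej <= rejected) break
    rejected <- n_rej
    if (n_rej >= k) k <- n_rej + 1L else break
    if (k >= N - 1L) break
  }
  if (rejected > 0) {
    x2 <- peirce_x2(N, max(1L, min(rejected, N - 2L)))
    keep[fin] <- dev <= sqrt(x2) * sdev
  }
  keep
}

#' Fit a gLMS intensity curve
#'
#' Least-squares fit of a saturating logistic in log10 concentration,
#' `I(c) = Imax * logistic((log10 c - mu) / s)` with the floor fixed at 0,
#' to intensity ratings in percent of the scale length.
#'
#' @param conc concentrations (M).
#' @param intensity ratings in \[0, 100\].
#' @return list of class `intensity_fit`: `imax`, `mu`, `s`, `range`
#'   (tested log10 range), `rss`, `flat` (TRUE when ratings carry no
#'   usable gradient and inversion is undefined).
#' @export
fit_intensity <- function(conc, intensity) {
  ok <- !is.na(conc) & !is.na(intensity)
  conc <- conc[ok]; intensity <- intensity[ok]
  if (length(unique(conc)) < 4) {
    stop("need intensity ratings at >= 4 concentration steps", call. = FALSE)
  }
  lc <- log10(conc)
  out <- list(imax = NA_real_, mu = NA_real_, s = NA_real_,
              range = range(lc), rss = NA_real_, flat = FALSE)
  class(out) <- "intensity_fit"
  if (max(intensity) - min(intensity) < 3 || stats::sd(intensity) < 1) {
    out$flat <- TRUE
    return(out)
  }
  ss <- function(par) {
    imax <- par[1]; mu <- par[2]; s <- exp(par[3])
    sum((intensity - imax * stats::plogis((lc - mu) / s))^2)
  }
  starts <- list(
    c(max(intensity) * 1.05, stats::median(lc), log(0.4)),
    c(min(100, max(intensity) * 1.2), stats::quantile(lc, .7), log(0.25)),
    c(80, stats::quantile(lc, .5), log(0.6)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(unlist(st), ss, method = "L-BFGS-B",
                   lower = c(5, min(lc) - 3, log(0.05)),
                   upper = c(130, max(lc) + 3, log(3))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    out$flat <- TRUE
    return(out)
  }
  out$imax <- best$par[1]; out$mu <- best$par[2]; out$s <- exp(best$par[3])
  out$rss <- best$value
  out
}

#' Invert an intensity curve at a gLMS scale percentage
#'
#' Solves `I(c) = pct` for the concentration at which the fitted intensity
#' curve crosses a labeled point of the scale (weak 6, moderate 17, strong
#' 34.7, very strong 52.5 percent of scale length). Solutions outside the
#' tested concentration range, or above the curve's saturation, are flagged
#' censored.
#'
#' @param fit an `intensity_fit`.
#' @param pct scale percentage(s) in (0, 100).
#' @return data.frame (pct, conc, censor) with censor in
#'   `"none"/"low"/"high"/"undefined"`.
#' @export
invert_intensity <- function(fit, pct = c(6, 17, 34.7, 52.5)) {
  out <- data.frame(pct = pct, conc = NA_real_, censor = "undefined",
                    stringsAsFactors = FALSE)
  if (isTRUE(fit$flat) || is.na(fit$imax)) return(out)
  for (i in seq_along(pct)) {
    if (pct[i] >= fit$imax) {
      out$censor[i] <- "high"
      next
    }
    lc <- fit$mu + fit$s * stats::qlogis(pct[i] / fit$imax)
    out$conc[i] <- 10^lc
    out$censor[i] <- if (lc < fit$range[1]) "low"
    else if (lc > fit$range[2]) "high" else "none"
  }
  out
}

#' Fold range of positive values
#'
#' max/min, the descriptive statistic used for phenotype spans (e.g. a
#' 25-fold recognition-threshold range).
#'
#' @param values positive numeric vector.
#' @return list `ratio` (exact) and `fold` (rounded to nearest integer).
#' @export
fold_range <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1 || any(values <= 0)) {
    stop("`values` must be positive and non-empty", call. = FALSE)
  }
  r <- max(values) / min(values)
  list(ratio = r, fold = round(r))
}

#' Build the phenotype table from raw trials
#'
#' Per subject x compound x repetition: fits the 4-AFC detection and
#' yes/no recognition psychometric functions and the gLMS intensity curve,
#' inverts the latter at the weak/moderate/strong/very-strong scale points,
#' and flags outliers per compound x measure across subject-repetition
#' cells by Peirce's criterion on log10 concentrations. Censored values
#' are clamped to the tested series boundary (flag retained) when
#' `clamp_censored` is TRUE.
#'
#' @param trials trial table as from [simulate_psychophysics()].
#' @param pcts gLMS scale percentages for the intensity measures.
#' @param clamp_censored clamp censored concentrations to the series range.
#' @param pool_repetitions fit a single pooled series per subject x
#'   compound instead of per repetition.
#' @return data.frame (subject, compound, repetition, measure, conc,
#'   censor, outlier) with measure in detection, recognition, weak,
#'   moderate, strong, very_strong.
#' @export
phenotype_table <- function(trials, pcts = c(weak = 6, moderate = 17,
                                             strong = 34.7, very_strong = 52.5),
                            clamp_censored = TRUE, pool_repetitions = FALSE) {
  key <- if (pool_repetitions) {
    interaction(trials$subject, trials$compound, drop = TRUE)
  } else {
    interaction(trials$subject, trials$compound, trials$repetition, drop = TRUE)
  }
  rows <- lapply(split(trials, key), function(d) {
    cmin <- min(d$conc); cmax <- max(d$conc)
    clamp <- function(v, censor) {
      if (!clamp_censored || censor == "none" || is.na(v) && censor == "undefined")
        return(v)
      if (censor == "low") max(v, cmin, na.rm = TRUE)
      else if (censor == "high") min(v, cmax, na.rm = TRUE) else v
    }
    det <- fit_psychometric(d$conc, d$correct_4afc, "detection")
    rec <- fit_psychometric(d$conc, d$recognized, "recognition")
    int <- fit_intensity(d$conc, d$intensity)
    inv <- invert_intensity(int, unname(pcts))
    conc <- c(clamp(det$threshold, det$censor),
              clamp(rec$threshold, rec$censor),
              mapply(function(v, cs) clamp(if (is.na(v) && cs == "high") cmax
                                           else v, cs),
                     inv$conc, inv$censor))
    data.frame(subject = d$subject[1], compound = d$compound[1],
               repetition = if (pool_repetitions) NA_integer_ else d$repetition[1],
               measure = c("detection", "recognition", names(pcts)),
               conc = unname(conc),
               censor = c(det$censor, rec$censor, inv$censor),
               stringsAsFactors = FALSE)
  })
  ph <- do.call(rbind, rows)
  rownames(ph) <- NULL
  ph$outlier <- FALSE
  for (cm in unique(ph$compound)) for (ms in unique(ph$measure)) {
    i <- which(ph$compound == cm & ph$measure == ms & !is.na(ph$conc))
    if (length(i) >= 3) {
      ph$outlier[i] <- !peirce_outliers(log10(ph$conc[i]))
    }
  }
  ph
}
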