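#' Simulate 4-AFC psychophysics trials
#'
#' Generates the raw trial table of the ascending four-alternative
#' forced-choice procedure with yes/no bitterness recognition and gLMS
#' intensity ratings. Per concentration step, 4-AFC correctness is drawn
#' with `P(correct) = guess + (1 - guess) * F(log10 c; mu_det, slope)`,
#' recognition with `P(yes) = F(log10 c; mu_rec, slope)`, and intensity as
#' a saturating logistic of log10 concentration plus Gaussian noise clipped
#' to \[0, 100\]. Detection sits `det_shift` log10 units below recognition.
#' Three repetitions per subject and compound share the subject's latent
#' threshold (no repetition effect).
#'
#' @param cohort a `tas2r_cohort`.
#' @param seed integer seed.
#' @param recognition `"all"`: the yes/no question is posed at every step;
#'   `"chosen"`: only where the 4-AFC choice was correct (the alternative
#'   reading of the procedure), other steps get `NA`.
#' @param latent optional precomputed [latent_sensitivity()] table.
#' @return data.frame (subject, compound, repetition, step, conc,
#'   correct_4afc, recognized, intensity) — one row per cell.
#' @export
simulate_psychophysics <- function(cohort, seed = cohort$scenario$seed,
                                   recognition = c("all", "chosen"),
                                   latent = NULL) {
  recognition <- match.arg(recognition)
  sc <- cohort$scenario
  if (is.null(latent)) {
    latent <- latent_sensitivity(cohort, seed = child_seed(seed, "latent"))
  }
  out <- vector("list", nrow(sc$psych_design))
  for (ci in seq_len(nrow(sc$psych_design))) {
    pd <- sc$psych_design[ci, ]
    cm <- pd$compound
    conc <- geometric_series(pd$start, pd$ratio, pd$n_steps)
    lc <- log10(conc)
    lat <- latent$latent_log10[latent$compound == cm][
      match(cohort$subjects, latent$subject[latent$compound == cm])]
    grid <- expand.grid(step = seq_len(pd$n_steps),
                        repetition = seq_len(pd$n_reps),
                        subject_i = seq_along(cohort$subjects),
                        KEEP.OUT.ATTRS = FALSE)
    mu_rec <- lat[grid$subject_i]
    mu_det <- mu_rec - pd$det_shift
    lcg <- lc[grid$step]
    out[[ci]] <- with_local_seed(child_seed(seed, paste0("psy_", cm)), {
      imax <- pmin(100, stats::rnorm(length(cohort$subjects), pd$imax_mean, pd$imax_sd))
      mu_int <- lat + pd$int_shift
      p_cor <- pd$guess + (1 - pd$guess) * stats::plogis(pd$slope_det * (lcg - mu_det))
      p_yes <- stats::plogis(pd$slope_rec * (lcg - mu_rec))
      correct <- stats::rbinom(nrow(grid), 1L, p_cor)
      recog <- stats::rbinom(nrow(grid), 1L, p_yes)
      ity <- imax[grid$subject_i] *
        stats::plogis((lcg - mu_int[grid$subject_i]) / pd$int_slope) +
        stats::rnorm(nrow(grid), 0, pd$int_noise_sd)
      ity <- pmin(100, pmax(0, ity))
      if (recognition == "chosen") recog[correct == 0L] <- NA_integer_
      data.frame(subject = cohort$subjects[grid$subject_i], compound = cm,
                 repetition = grid$repetition, step = grid$step,
                 conc = conc[grid$step], correct_4afc = correct,
                 recognized = recog, intensity = ity,
                 stringsAsFactors = FALSE)
    })
  }
  do.call(rbind, out)
}

#' Simulate calcium-imaging plates
#'
#' Generates raw fluorescence wells for every receptor construct in the
#' scenario's receptor table, plus matched empty-vector wells per
#' (day, compound, concentration) and positive-control wells per day. One
#' replicate per construct/concentration per day across `n_days` days (six
#' replicates by default). Raw peak fluorescence is
#' `F = F0 * (1 + g_d * (response + artefact) + noise)` with a per-day gain
#' `g_d`, a receptor-independent artefact shared with the empty vector, and
#' well-to-well baseline variation in `F0`.
#'
#' @param scenario a `tas2r_scenario`.
#' @param seed integer seed.
#' @param compounds subset of compounds (default: all in receptor table).
#' @return data.frame (day, well, construct, gene, allele, compound, conc,
#'   F, F0).
#' @export
simulate_plates <- function(scenario, seed = scenario$seed, compounds = NULL) {
  rt <- scenario$receptor_table
  if (nrow(rt) == 0) stop("receptor table is empty", call. = FALSE)
  if (!is.null(compounds)) rt <- rt[rt$compound %in% compounds, , drop = FALSE]
  rt <- rt[rt$allele != "DEL", , drop = FALSE]   # no construct for a deleted gene
  pl <- scenario$plate_design
  conc <- pl$conc
  rows <- list(); k <- 0L
  with_local_seed(seed, {
    day_gain <- stats::rnorm(pl$n_days, 1, pl$day_sd)
    day_gain <- pmax(0.1, day_gain)
    for (d in seq_len(pl$n_days)) {
      for (j in seq_len(pl$n_pc_wells)) {
        k <- k + 1L
        rows[[k]] <- data.frame(day = d, construct = "positive_control",
                                gene = NA, allele = NA, compound = NA,
                                conc = NA_real_, resp = pl$pc_response,
                                stringsAsFactors = FALSE)
      }
      for (cm in unique(rt$compound)) {
        rti <- rt[rt$compound == cm, ]
        art <- pl$artefact_amp * conc / max(conc)
        k <- k + 1L
        rows[[k]] <- data.frame(day = d, construct = "empty_vector",
                                gene = NA, allele = NA, compound = cm,
                                conc = conc, resp = art, stringsAsFactors = FALSE)
        for (r in seq_len(nrow(rti))) {
          amp <- rti$amplitude[r]
          resp <- if (amp <= 0 || is.na(rti$ec50[r])) rep(0, length(conc)) else
            amp / (1 + (rti$ec50[r] / conc)^rti$hill_n[r])
          k <- k + 1L
          rows[[k]] <- data.frame(
            day = d, construct = paste(rti$gene[r], rti$allele[r], sep = "-"),
            gene = rti$gene[r], allele = rti$allele[r], compound = cm,
            conc = conc, resp = resp + art, stringsAsFactors = FALSE)
        }
      }
    }
    plates <- do.call(rbind, rows)
    n <- nrow(plates)
    plates$F0 <- pmax(1, stats::rnorm(n, pl$f0_mean, pl$f0_sd))
    noise <- stats::rnorm(n, 0, pl$noise_sd)
    plates$F <- plates$F0 * (1 + day_gain[plates$day] * plates$resp + noise)
    plates$resp <- NULL
    plates$well <- sprintf("W%05d", seq_len(n))
    plates[, c("day", "well", "construct", "gene", "allele", "compound",
               "conc", "F", "F0")]
  })
}
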