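#' Default protein SERS peak table
#'
#' The 24 characteristic protein bands used throughout the package, with
#' tentative amino-acid / backbone assignments, base amplitudes (relative
#' units, chosen so the four strongest bands sit at 1003, 1266, 1449 and
#' 1679 cm^-1), Lorentzian FWHM, the direction of the pooled NPC-vs-normal
#' intensity shift, and whether the band carries a linear stage trend
#' (phenylalanine bands at 1003 and 1033 cm^-1).
#'
#' @return data.frame with columns \code{shift}, \code{assignment},
#'   \code{base_amplitude}, \code{fwhm}, \code{direction}
#'   (\code{up}/\code{down}/\code{none}), \code{stage_trend}
#'   (\code{none}/\code{linear}).
#' @export
default_peak_table <- function() {
  tab <- data.frame(
    shift = c(490, 548, 625, 645, 679, 740, 756, 836, 851, 881, 936, 1003,
              1033, 1046, 1124, 1180, 1209, 1266, 1313, 1449, 1523, 1553,
              1616, 1679),
    assignment = c(
      "Arginine", "Tryptophan", "Glutathione", "Glutathione", "Histidine",
      "Glutamate", "Tryptophan", "Proline", "Alanine/Proline/Arginine",
      "Arginine", "Glycine", "Phenylalanine", "Phenylalanine", "Tryptophan",
      "Valine", "Tyrosine", "Tyrosine", "Amide III/Tryptophan", "Glutamate",
      "Alanine", "Glutamate", "Tryptophan", "Serine", "Amide I"),
    base_amplitude = c(0.35, 0.40, 0.38, 0.35, 0.30, 0.33, 0.45, 0.35, 0.45,
                       0.40, 0.32, 1.00, 0.50, 0.45, 0.35, 0.38, 0.40, 0.80,
                       0.45, 0.75, 0.35, 0.42, 0.30, 0.70),
    fwhm = 10,
    stringsAsFactors = FALSE)
  up <- c(548, 756, 1003, 1033, 1046, 1124, 1266, 1553, 1679)
  down <- c(490, 625, 645, 740, 836, 851, 881, 936, 1180, 1209, 1313, 1449, 1523)
  tab$direction <- ifelse(tab$shift %in% up, "up",
                          ifelse(tab$shift %in% down, "down", "none"))
  tab$stage_trend <- ifelse(tab$shift %in% c(1003, 1033), "linear", "none")
  tab
}

validate_peak_table <- function(peaks) {
  need <- c("shift", "base_amplitude", "fwhm", "direction", "stage_trend")
  if (!all(need %in% names(peaks)))
    stop("peak table missing columns: ",
         paste(setdiff(need, names(peaks)), collapse = ", "))
  stopifnot(all(peaks$base_amplitude > 0), all(peaks$fwhm > 0),
            all(peaks$direction %in% c("up", "down", "none")),
            all(peaks$stage_trend %in% c("none", "linear")))
  invisible(peaks)
}

#' Class effect model for the synthetic cohort
#'
#' @param effect_size fractional amplitude change of each affected band for
#'   pooled NPC vs normal (applied with the band's configured direction).
#' @param stage_step per-stage fractional increment for linear-trend bands;
#'   stage s in I..IV multiplies the band by \code{1 + stage_step * s}.
#' @param subject_sd between-subject lognormal sdlog of per-band amplitude.
#' @export
class_effect_model <- function(effect_size = 0.15, stage_step = 0.05,
                               subject_sd = 0.10) {
  stopifnot(effect_size >= 0, effect_size < 1, stage_step >= 0, subject_sd >= 0)
  structure(list(effect_size = effect_size, stage_step = stage_step,
                 subject_sd = subject_sd), class = "class_effect_model")
}

#' Simulation configuration
#'
#' Defaults reproduce the study cohort: 225 healthy, 120/249/291/279 NPC
#' stages I--IV (1164 subjects, one spectrum each).
#'
#' @param cohort_sizes named integer vector over the five classes.
#' @param grid Raman shift axis (default 400--1800 cm^-1 at 2 cm^-1).
#' @param baseline_order polynomial order of the fluorescence baseline.
#' @param baseline_range range (relative to the subject's maximum band
#'   height) from which the baseline amplitude is drawn uniformly; set to
#'   \code{c(0, 0)} for no baseline.
#' @param noise_sd additive Gaussian noise sd, relative to the scaled
#'   spectrum's maximum band height.
#' @param scale_sd lognormal sdlog of the global multiplicative factor
#'   (laser power / concentration variation).
#' @param seed master seed; each subject uses substream \code{seed + index}.
#' @export
simulation_config <- function(cohort_sizes = c(normal = 225, I = 120, II = 249,
                                               III = 291, IV = 279),
                              grid = raman_grid(),
                              baseline_order = 5,
                              baseline_range = c(0.5, 2),
                              noise_sd = 0.01,
                              scale_sd = 0.15,
                              seed = 1L) {
  stopifnot(all(cohort_sizes >= 0),
            all(names(cohort_sizes) %in% sers_classes()),
            baseline_order >= 1, length(baseline_range) == 2,
            all(baseline_range >= 0), baseline_range[1] <= baseline_range[2],
            noise_sd >= 0, scale_sd >= 0)
  validate_grid(grid)
  structure(list(cohort_sizes = cohort_sizes, grid = as.numeric(grid),
                 baseline_order = baseline_order,
                 baseline_range = baseline_range, noise_sd = noise_sd,
                 scale_sd = scale_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

# Lorentzian line: unit peak height, half-width gamma = fwhm / 2
lorentzian <- function(x, center, fwhm) {
  g2 <- (fwhm / 2)^2
  g2 / ((x - center)^2 + g2)
}

# per-band amplitudes for a class label ("NPC" = pooled, stage index 0)
class_amplitudes <- function(label, peaks, effects) {
  label <- as.character(label)
  stages <- c(I = 1, II = 2, III = 3, IV = 4)
  if (!label %in% c("normal", "NPC", names(stages)))
    stop("unknown class label: ", label)
  a <- peaks$base_amplitude
  if (label != "normal") {
    a <- a * ifelse(peaks$direction == "up", 1 + effects$effect_size,
                    ifelse(peaks$direction == "down",
                           1 - effects$effect_size, 1))
    if (label %in% names(stages)) {
      s <- stages[[label]]
      a <- a * ifelse(peaks$stage_trend == "linear",
                      1 + effects$stage_step * s, 1)
    }
  }
  a
}

#' Noise-free expected spectrum of a class
#'
#' Sum of Lorentzian bands with class-adjusted amplitudes: affected bands
#' are scaled by \code{1 +/- effect_size} for any NPC label, and
#' linear-trend bands additionally by \code{1 + stage_step * s} for stage
#' s in I..IV. Label \code{"NPC"} gives the pooled NPC class (direction
#' shifts only). No baseline, no noise; deterministic.
#'
#' @param label one of \code{"normal"}, \code{"NPC"}, \code{"I"}..\code{"IV"}.
#' @param peaks peak table (see \code{\link{default_peak_table}}).
#' @param effects a \code{\link{class_effect_model}}.
#' @param grid Raman shift axis.
#' @return single-spectrum \code{spectrum_set}.
#' @export
expected_spectrum <- function(label, peaks = default_peak_table(),
                              effects = class_effect_model(),
                              grid = raman_grid()) {
  validate_peak_table(peaks)
  a <- class_amplitudes(label, peaks, effects)
  y <- numeric(length(grid))
  for (j in seq_len(nrow(peaks)))
    y <- y + a[j] * lorentzian(grid, peaks$shift[j], peaks$fwhm[j])
  lab <- if (label %in% sers_classes()) label else NULL
  spectrum_set(grid, matrix(y, ncol = 1), labels = lab,
               sample_ids = paste0("expected_", label))
}

# one subject's raw spectrum; all randomness comes from subject_seed
simulate_one <- function(label, config, peaks, effects, subject_seed) {
  set.seed(as.integer(subject_seed))
  grid <- config$grid
  a <- class_amplitudes(label, peaks, effects) *
    exp(stats::rnorm(nrow(peaks), 0, effects$subject_sd))
  mu <- numeric(length(grid))
  for (j in seq_len(nrow(peaks)))
    mu <- mu + a[j] * lorentzian(grid, peaks$shift[j], peaks$fwhm[j])
  # smooth non-negative fluorescence baseline: random polynomial shifted up
  x <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  coefs <- stats::rnorm(config$baseline_order + 1)
  p <- drop(outer(x, 0:config$baseline_order, `^`) %*% coefs)
  amp <- stats::runif(1, config$baseline_range[1], config$baseline_range[2]) *
    max(mu)
  bl <- amp * (p - min(p) + 0.05) / max(p - min(p) + 0.05)
  scale <- exp(stats::rnorm(1, 0, config$scale_sd))
  y <- (mu + bl) * scale
  y <- y + stats::rnorm(length(grid), 0, config$noise_sd * max(mu) * scale)
  pmax(y, 0)
}

#' Simulate one labeled SERS spectrum
#'
#' Expected class spectrum with per-band lognormal subject variation, plus
#' a smooth non-negative polynomial fluorescence baseline, times a global
#' lognormal intensity scale, plus additive Gaussian noise; clipped at 0.
#'
#' @inheritParams expected_spectrum
#' @param config a \code{\link{simulation_config}}.
#' @param subject_seed integer seed for this subject's random substream.
#' @return single-spectrum \code{spectrum_set}.
#' @export
simulate_spectrum <- function(label, config = simulation_config(),
                              peaks = default_peak_table(),
                              effects = class_effect_model(),
                              subject_seed = config$seed) {
  validate_peak_table(peaks)
  y <- simulate_one(label, config, peaks, effects, subject_seed)
  lab <- if (label %in% sers_classes()) label else NULL
  spectrum_set(config$grid, matrix(y, ncol = 1), labels = lab,
               sample_ids = paste0(label, "_", subject_seed))
}

#' Simulate a full labeled cohort
#'
#' One spectrum per subject. Subject i (in class-block order normal, I, II,
#' III, IV) uses the random substream \code{config$seed + i}, so the cohort
#' is reproducible and independent of generation order.
#'
#' @inheritParams simulate_spectrum
#' @return labeled \code{spectrum_set} with \code{class_counts} equal to
#'   \code{config$cohort_sizes}.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            peaks = default_peak_table(),
                            effects = class_effect_model()) {
  validate_peak_table(peaks)
  sizes <- config$cohort_sizes
  labels <- rep(names(sizes), times = sizes)
  n <- length(labels)
  out <- matrix(0, nrow = length(config$grid), ncol = n)
  for (i in seq_len(n))
    out[, i] <- simulate_one(labels[i], config, peaks, effects,
                             config$seed + i)
  ids <- paste0(labels, "_", stats::ave(seq_len(n), labels, FUN = seq_along))
  spectrum_set(config$grid, out, labels = labels, sample_ids = ids)
}
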