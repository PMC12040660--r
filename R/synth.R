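#' Describe one vibrational peak
#'
#' @param center peak position (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param amplitude peak height (a.u.), >= 0.
#' @param shape `"lorentzian"` (the usual Raman line shape) or `"gaussian"`.
#' @return one-row tibble describing the peak.
#' @export
peak_spec <- function(center, fwhm, amplitude, shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (!is.finite(fwhm) || fwhm <= 0) abort("fwhm must be > 0")
  if (!is.finite(amplitude) || amplitude < 0) abort("amplitude must be >= 0")
  tibble(center = center, fwhm = fwhm, amplitude = amplitude, shape = shape)
}

#' Default serum SERS peak table
#'
#' Roughly a dozen Lorentzian bands at positions commonly reported in
#' near-infrared SERS of human serum, including the discriminative bands at
#' 632, 728 and 1062 cm^-1. Positions, widths and relative heights are
#' generator configuration, chosen to give a serum-like band pattern; they
#' carry no claim about any particular instrument.
#'
#' @return tibble of peak specifications (see [peak_spec()]).
#' @export
default_serum_peaks <- function() {
  dplyr::bind_rows(
    peak_spec(495,  18, 0.35),
    peak_spec(590,  16, 0.30),
    peak_spec(632,  16, 0.30),
    peak_spec(728,  18, 0.28),
    peak_spec(810,  14, 0.25),
    peak_spec(890,  16, 0.30),
    peak_spec(960,  14, 0.40),
    peak_spec(1004, 10, 0.80),
    peak_spec(1062, 24, 0.26),
    peak_spec(1135, 18, 0.35),
    peak_spec(1205, 16, 0.30),
    peak_spec(1330, 20, 0.45),
    peak_spec(1445, 22, 0.40),
    peak_spec(1585, 20, 0.40),
    peak_spec(1650, 24, 0.45)
  )
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study design the package targets: 48 Target
#' (patient) and 30 Control (healthy donor) subjects, 3 replicate spectra
#' per serum sample, a 400-1800 cm^-1 axis at 2 cm^-1 steps (701 channels),
#' sharp Lorentzian peaks on a smooth autofluorescent baseline, additive
#' Gaussian noise sized so the signal-to-noise ratio is on the order of 50,
#' and between-group intensity differences confined to the effect bands at
#' 632, 728 and 1062 cm^-1.
#'
#' @param n_target,n_control subject counts per group (>= 1).
#' @param replicates_per_subject spectra recorded per subject (>= 1).
#' @param axis_start,axis_stop,axis_step wavenumber axis (cm^-1).
#' @param shared_peaks tibble of peaks present in both groups
#'   ([default_serum_peaks()]).
#' @param effect_bands list of `c(center, width)` pairs (cm^-1); peaks whose
#'   center falls inside a band have their amplitude multiplied by
#'   `effect_ratio` in the Target group.
#' @param effect_ratio multiplicative Target/Control amplitude ratio at the
#'   effect bands (> 0; 1 = null cohort with no group difference).
#' @param subject_sd between-subject log-amplitude standard deviation
#'   (dimensionless). Each subject draws one global factor and one factor
#'   per peak, all `exp(N(0, subject_sd))`, shared across its replicates, so
#'   replicate spectra are correlated within subject.
#' @param replicate_sd within-subject (replicate-level) per-peak
#'   log-amplitude standard deviation, emulating the band-intensity
#'   variability between repeated SERS acquisitions of one serum sample
#'   (enhancement heterogeneity across the dried substrate).
#' @param noise_sd additive per-channel Gaussian noise sd (a.u., >= 0).
#' @param baseline_scale amplitude of the smooth autofluorescent baseline
#'   (a.u.); its per-subject scale is itself log-normally jittered with sd
#'   `subject_sd`.
#' @param drop_spectra number of Control replicate spectra to drop from the
#'   end of the cohort (default 0; set to 2 to mimic a 90 - 2 = 88 spectrum
#'   control arm).
#' @param seed integer RNG seed; the whole cohort is a pure function of the
#'   configuration.
#' @return a validated configuration list of class `cohort_config`.
#' @export
cohort_config <- function(n_target = 48, n_control = 30,
                          replicates_per_subject = 3,
                          axis_start = 400, axis_stop = 1800, axis_step = 2,
                          shared_peaks = default_serum_peaks(),
                          effect_bands = list(c(632, 10), c(728, 14), c(1062, 28)),
                          effect_ratio = 2,
                          subject_sd = 0.30,
                          replicate_sd = 0.25,
                          noise_sd = 0.02,
                          baseline_scale = 0.6,
                          drop_spectra = 0,
                          seed = 1L) {
  cfg <- list(
    n_target = as.integer(n_target), n_control = as.integer(n_control),
    replicates_per_subject = as.integer(replicates_per_subject),
    axis_start = axis_start, axis_stop = axis_stop, axis_step = axis_step,
    shared_peaks = as_tibble(shared_peaks), effect_bands = effect_bands,
    effect_ratio = effect_ratio, subject_sd = subject_sd,
    replicate_sd = replicate_sd,
    noise_sd = noise_sd, baseline_scale = baseline_scale,
    drop_spectra = as.integer(drop_spectra), seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_target < 1 || n_control < 1 || replicates_per_subject < 1) {
      abort("subject and replicate counts must be >= 1")
    }
    if (axis_step <= 0) abort("axis_step must be > 0")
    if (axis_start >= axis_stop) abort("axis_start must be < axis_stop")
    if (effect_ratio <= 0) abort("effect_ratio must be > 0")
    if (noise_sd < 0) abort("noise_sd must be >= 0")
    if (subject_sd < 0) abort("subject_sd must be >= 0")
    if (replicate_sd < 0) abort("replicate_sd must be >= 0")
    if (drop_spectra < 0) abort("drop_spectra must be >= 0")
    if (any(shared_peaks$fwhm <= 0) || any(shared_peaks$amplitude < 0)) {
      abort("invalid peak table: fwhm must be > 0 and amplitude >= 0")
    }
    if (any(shared_peaks$center < axis_start | shared_peaks$center > axis_stop)) {
      abort("peak centers must lie within the axis range")
    }
  })
  cfg
}

#' Build a uniform wavenumber axis
#'
#' @param start,stop axis limits (cm^-1), `start < stop`.
#' @param step channel spacing (cm^-1), > 0.
#' @return strictly increasing numeric vector starting at `start` with the
#'   last point `<= stop`.
#' @export
make_axis <- function(start, stop, step) {
  if (!is.finite(step) || step <= 0) abort("step must be > 0")
  if (!is.finite(start) || !is.finite(stop) || stop <= start) {
    abort("need start < stop")
  }
  seq(start, stop, by = step)
}

cohort_axis <- function(cfg) make_axis(cfg$axis_start, cfg$axis_stop, cfg$axis_step)

peak_profile <- function(axis, center, fwhm, shape) {
  if (shape == "lorentzian") {
    g <- fwhm / 2
    g^2 / ((axis - center)^2 + g^2)
  } else {
    exp(-4 * log(2) * (axis - center)^2 / fwhm^2)
  }
}

# broad smooth autofluorescence shape: low-order polynomial plus one wide
# Gaussian bump; unit amplitude before baseline_scale is applied
baseline_shape <- function(axis) {
  u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
  0.8 - 0.5 * u + 0.35 * u^2 + 1.1 * exp(-(axis - 1150)^2 / (2 * 330^2))
}

in_effect_band <- function(centers, effect_bands) {
  hit <- rep(FALSE, length(centers))
  for (b in effect_bands) {
    hit <- hit | (centers >= b[1] - b[2] / 2 & centers <= b[1] + b[2] / 2)
  }
  hit
}

#' Simulate one spectrum
#'
#' Returns `baseline + subject_factor * sum(peaks) + noise`, with the
#' amplitudes of peaks lying in an effect band multiplied by
#' `cfg$effect_ratio` when `group == "Target"`. Deterministic given `seed`.
#'
#' @param cfg a [cohort_config()].
#' @param group `"Target"` or `"Control"`.
#' @param subject_factor multiplicative amplitude factor(s): a scalar, or a
#'   vector with one entry per peak in `cfg$shared_peaks` (> 0).
#' @param baseline_factor multiplicative factor on `cfg$baseline_scale`.
#' @param seed integer seed for the additive noise.
#' @return numeric intensity vector over `cohort_axis(cfg)`.
#' @export
synth_spectrum <- function(cfg, group, subject_factor = 1, baseline_factor = 1,
                           seed = cfg$seed) {
  group <- match.arg(group, .group_levels)
  if (any(subject_factor <= 0)) abort("subject_factor must be > 0")
  axis <- cohort_axis(cfg)
  pk <- cfg$shared_peaks
  fac <- rep_len(subject_factor, nrow(pk))
  amp <- pk$amplitude * fac
  if (group == "Target") {
    hit <- in_effect_band(pk$center, cfg$effect_bands)
    amp[hit] <- amp[hit] * cfg$effect_ratio
  }
  signal <- numeric(length(axis))
  for (i in seq_len(nrow(pk))) {
    signal <- signal + amp[i] * peak_profile(axis, pk$center[i], pk$fwhm[i], pk$shape[i])
  }
  base <- cfg$baseline_scale * baseline_factor * baseline_shape(axis)
  noise <- if (cfg$noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(length(axis), 0, cfg$noise_sd))
  } else {
    0
  }
  base + signal + noise
}

#' Generate a synthetic SERS cohort
#'
#' Draws per-subject amplitude factors (one global and one per peak, all
#' log-normal with sd `subject_sd`, shared across the subject's replicates)
#' and a per-subject baseline scale, then simulates
#' `replicates_per_subject` spectra per subject, each with its own per-peak
#' log-normal replicate factors (sd `replicate_sd`) and independent
#' additive noise. The result is bit-identical for identical
#' configurations.
#'
#' @param cfg a [cohort_config()].
#' @return a spectra tibble (see [spectra_tbl()]) with
#'   `n_target * replicates` Target rows followed by Control rows (minus
#'   `drop_spectra` trailing Control rows).
#' @export
generate_cohort <- function(cfg) {
  validate_cohort_config(cfg)
  axis <- cohort_axis(cfg)
  n_pk <- nrow(cfg$shared_peaks)
  subjects <- tibble(
    subject_id = c(sprintf("T%02d", seq_len(cfg$n_target)),
                   sprintf("C%02d", seq_len(cfg$n_control))),
    group = rep(.group_levels, c(cfg$n_target, cfg$n_control))
  )
  reps <- cfg$replicates_per_subject
  withr::with_seed(cfg$seed, {
    rows <- purrr::pmap(subjects, function(subject_id, group) {
      gfac <- exp(stats::rnorm(1, 0, cfg$subject_sd))
      pfac <- exp(stats::rnorm(n_pk, 0, cfg$subject_sd))
      bfac <- exp(stats::rnorm(1, 0, cfg$subject_sd))
      rfac <- matrix(exp(stats::rnorm(n_pk * reps, 0, cfg$replicate_sd)), n_pk, reps)
      noise_seeds <- sample.int(.Machine$integer.max - 1L, reps)
      spec <- vapply(seq_len(reps), function(r) {
        synth_spectrum(cfg, group, subject_factor = gfac * pfac * rfac[, r],
                       baseline_factor = bfac, seed = noise_seeds[r])
      }, numeric(length(axis)))
      list(
        meta = tibble(
          spectrum_id = sprintf("%s_r%d", subject_id, seq_len(reps)),
          subject_id = subject_id, group = group
        ),
        intens = t(spec)
      )
    })
  })
  meta <- dplyr::bind_rows(purrr::map(rows, "meta"))
  intens <- do.call(rbind, purrr::map(rows, "intens"))
  if (cfg$drop_spectra > 0) {
    if (cfg$drop_spectra >= cfg$replicates_per_subject) {
      abort("drop_spectra must leave every subject at least one spectrum")
    }
    keep <- seq_len(nrow(meta) - cfg$drop_spectra)
    meta <- meta[keep, ]
    intens <- intens[keep, , drop = FALSE]
  }
  spectra_tbl(axis, intens, meta)
}
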