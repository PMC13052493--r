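# Synthetic generator for occlusion-protocol FD-NIRS recordings: forearm
# cohort anatomies, programmed per-layer hemodynamic schedules, and noisy
# per-channel AC/phase time series with instrument gains, sampled at 2.4 Hz.

#' Forearm cohort anatomies
#'
#' The 14 reference anatomies (adipose tissue thickness ATT = L1, muscle
#' tissue thickness MTT = L2, bone depth = L1 + L2, in mm) spanning
#' ATT 1.5-9.5 mm and bone depth 14-26 mm.
#'
#' @return Data frame `id, att_mm, mtt_mm, bone_depth_mm`.
#' @export
cohort_anatomy <- function() {
  att <- c(3.0, 4.0, 2.5, 3.7, 4.5, 6.5, 7.0, 6.2, 5.0, 1.7, 1.5, 2.0,
           9.5, 8.0)
  mtt <- c(11.0, 10.5, 12.5, 13.3, 14.0, 13.0, 13.5, 14.5, 16.0, 19.8,
           20.5, 21.5, 15.0, 18.0)
  data.frame(id = seq_along(att), att_mm = att, mtt_mm = mtt,
             bone_depth_mm = att + mtt)
}

#' Generate a cohort of anatomies
#'
#' `n = 14` returns the reference cohort exactly; other sizes sample ATT and
#' bone depth uniformly within the cohort ranges (ATT 1.5-9.5 mm, bone depth
#' 14-26 mm), seeded for reproducibility.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed used when sampling.
#' @return Data frame `id, att_mm, mtt_mm, bone_depth_mm`.
#' @export
generate_cohort <- function(n = 14, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (n == 14) return(cohort_anatomy())
  set.seed(seed)
  att <- stats::runif(n, 1.5, 9.5)
  bone <- pmax(stats::runif(n, 14, 26), att + 4)
  data.frame(id = seq_len(n), att_mm = att, mtt_mm = bone - att,
             bone_depth_mm = bone)
}

#' Instrument model: gains, offsets and noise
#'
#' Per-source and per-detector amplitude gain factors and phase offsets
#' (exercising the dual-slope self-calibration property), plus additive
#' Gaussian noise: relative amplitude SD and absolute phase SD per sample,
#' independent across channels and wavelengths.
#'
#' @param source_gain,detector_gain Positive amplitude factors, length 2
#'   (sources 1, 2 / detectors A, B).
#' @param source_phase,detector_phase Phase offsets, rad, length 2.
#' @param amp_noise_rel Relative AC amplitude noise SD (default 0.002).
#' @param phase_noise_rad Phase noise SD, rad (default 0.1 degree).
#' @param sampling_hz Sampling rate (default 2.4 Hz).
#' @return An object of class `instrument_model`.
#' @export
instrument_model <- function(source_gain = c(1, 1), detector_gain = c(1, 1),
                             source_phase = c(0, 0),
                             detector_phase = c(0, 0),
                             amp_noise_rel = 0.002,
                             phase_noise_rad = 0.1 * pi / 180,
                             sampling_hz = 2.4) {
  if (any(source_gain <= 0) || any(detector_gain <= 0))
    stop("amplitude gain factors must be positive")
  if (amp_noise_rel < 0 || phase_noise_rad < 0 || sampling_hz <= 0)
    stop("invalid noise or sampling parameters")
  structure(list(source_gain = source_gain, detector_gain = detector_gain,
                 source_phase = source_phase,
                 detector_phase = detector_phase,
                 amp_noise_rel = amp_noise_rel,
                 phase_noise_rad = phase_noise_rad,
                 sampling_hz = sampling_hz),
            class = "instrument_model")
}

#' Randomized instrument gains
#'
#' Draws source/detector amplitude gains log-uniform in `[0.5, 2]` and phase
#' offsets uniform in `[-0.5, 0.5]` rad; noise parameters as in
#' [instrument_model()].
#'
#' @param seed Integer seed.
#' @param ... Passed to [instrument_model()].
#' @return An `instrument_model`.
#' @export
random_instrument <- function(seed, ...) {
  set.seed(seed)
  instrument_model(source_gain = exp(stats::runif(2, log(0.5), log(2))),
                   detector_gain = exp(stats::runif(2, log(0.5), log(2))),
                   source_phase = stats::runif(2, -0.5, 0.5),
                   detector_phase = stats::runif(2, -0.5, 0.5), ...)
}

#' Named scenario library
#'
#' The programmed per-layer hemodynamic scenarios of the simulation studies:
#' `reference_venous` (dT = 5, 10, 0 uM in adipose, muscle, bone),
#' `reference_arterial` (dD = 5, 10, 0 uM; dO = -dD), `arterial_muscle`
#' (dD2 = 20 uM, dO2 = -20 uM, others 0), and constructors for the
#' adipose-variation families: venous dT1 swept 2-20 uM at fixed dT2, and
#' arterial dD1 swept 2-24 uM at fixed dD2 = 20 uM; the bone layer is inert
#' (dT3 = 0, dD3 = dO3 = 0) in all of them.
#'
#' @param dT2 Muscle total-hemoglobin accumulation for the venous family, uM.
#' @return A list of [hemodynamic_scenario()] objects and two constructor
#'   functions `venous_family(dT1)` and `arterial_family(dD1)`.
#' @export
default_scenarios <- function(dT2 = 10) {
  list(
    reference_venous = hemodynamic_scenario("venous", dT = c(5, 10, 0)),
    reference_arterial = hemodynamic_scenario("arterial",
                                                 dD = c(5, 10, 0)),
    arterial_muscle = hemodynamic_scenario("arterial", dD = c(0, 20, 0)),
    venous_family = function(dT1)
      hemodynamic_scenario("venous", dT = c(dT1, dT2, 0)),
    arterial_family = function(dD1)
      hemodynamic_scenario("arterial", dD = c(dD1, 20, 0))
  )
}

# fraction of the programmed amplitude reached at time t: zero through
# baseline, linear ramp over `ramp_s` of the occlusion, plateau, then
# exponential recovery (time constant 30 s)
.schedule_fraction <- function(time_s, protocol, ramp_s) {
  onset <- protocol$baseline_s
  release <- onset + protocol$occlusion_s
  f <- numeric(length(time_s))
  during <- time_s >= onset & time_s < release
  f[during] <- pmin((time_s[during] - onset) / ramp_s, 1)
  after <- time_s >= release
  f_rel <- min(protocol$occlusion_s / ramp_s, 1)
  f[after] <- f_rel * exp(-(time_s[after] - release) / 30)
  f
}

#' Simulate an occlusion-protocol channel recording
#'
#' For each time sample the programmed schedule is converted to per-layer
#' absorption changes (Beer's law), the layered media are perturbed and the
#' forward model evaluated at all four channels and both wavelengths; source
#' and detector gains/offsets are applied and seeded Gaussian noise is added.
#' The deterministic forward part is cached over unique schedule values, so
#' repeated noise realizations are cheap (see [resample_noise()]).
#'
#' @param media Per-wavelength list of layered truth media
#'   (e.g. [make_subject_pair()]).
#' @param scenario A [hemodynamic_scenario()] with one amplitude per layer.
#' @param protocol An [occlusion_protocol()] consistent with the scenario
#'   mode.
#' @param instrument An [instrument_model()].
#' @param seed Integer seed for the noise generator.
#' @param pair Wavelength pair, nm.
#' @param ramp_s Ramp time over which amplitudes are reached (default: the
#'   full occlusion phase).
#' @param geometry A [probe_geometry()].
#' @return Long-format data frame `time_s, channel, wavelength_nm, ac,
#'   phase_rad` with attribute `noiseless` (the pre-noise frame) and
#'   `meta` (schedule and instrument description).
#' @export
simulate_occlusion <- function(media, scenario, protocol, instrument =
                                 instrument_model(), seed = 1,
                               pair = c(690, 830), ramp_s = NULL,
                               geometry = probe_geometry()) {
  stopifnot(inherits(scenario, "hemodynamic_scenario"),
            inherits(protocol, "occlusion_protocol"),
            inherits(instrument, "instrument_model"))
  if (scenario$mode != protocol$mode)
    stop("scenario and protocol modes differ")
  if (length(scenario$amplitude) != length(media[[1]]$layers))
    stop("scenario has ", length(scenario$amplitude),
         " amplitudes for a ", length(media[[1]]$layers), "-layer medium")
  ramp_s <- ramp_s %||% protocol$occlusion_s

  total_s <- protocol$baseline_s + protocol$occlusion_s + protocol$recovery_s
  time_s <- seq(0, total_s, by = 1 / instrument$sampling_hz)
  f <- .schedule_fraction(time_s, protocol, ramp_s)
  change <- scenario_to_absorption(scenario, pair)

  chans <- geometry$channels
  r_short <- min(chans$distance_mm)
  r_long <- max(chans$distance_mm)

  # noiseless ac/phase per wavelength at the two distances, cached on the
  # unique schedule fractions
  uf <- sort(unique(f))
  resp <- lapply(seq_along(pair), function(i) {
    out <- vapply(uf, function(fi) {
      m <- perturb_mua(media[[i]], change[, i] * fi)
      rr <- layered_fd_reflectance(m, c(r_short, r_long))
      c(rr$ac, rr$phase)
    }, numeric(4))
    idx <- match(f, uf)
    list(ac = t(out[1:2, idx]), phase = t(out[3:4, idx]))  # [time, dist]
  })

  src_idx <- match(chans$source, c("1", "2"))
  det_idx <- match(chans$detector, c("A", "B"))
  dist_idx <- match(chans$distance_mm, c(r_short, r_long))

  set.seed(seed)
  rows <- list()
  clean <- list()
  for (i in seq_along(pair)) {
    for (j in seq_len(nrow(chans))) {
      ac0 <- resp[[i]]$ac[, dist_idx[j]] *
        instrument$source_gain[src_idx[j]] *
        instrument$detector_gain[det_idx[j]]
      ph0 <- resp[[i]]$phase[, dist_idx[j]] +
        instrument$source_phase[src_idx[j]] +
        instrument$detector_phase[det_idx[j]]
      ac <- ac0 * (1 + stats::rnorm(length(time_s), 0,
                                    instrument$amp_noise_rel))
      ph <- ph0 + stats::rnorm(length(time_s), 0,
                               instrument$phase_noise_rad)
      rows[[length(rows) + 1]] <- data.frame(
        time_s = time_s, channel = chans$channel[j],
        wavelength_nm = pair[i], ac = ac, phase_rad = ph)
      clean[[length(clean) + 1]] <- data.frame(
        time_s = time_s, channel = chans$channel[j],
        wavelength_nm = pair[i], ac = ac0, phase_rad = ph0)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "noiseless") <- do.call(rbind, clean)
  attr(out, "meta") <- list(mode = scenario$mode,
                            amplitude_uM = scenario$amplitude,
                            ramp_s = ramp_s, seed = seed, pair = pair)
  out
}

#' Fresh noise realization of a simulated recording
#'
#' Re-applies seeded Gaussian noise to the cached noiseless channels of a
#' [simulate_occlusion()] result, without re-running the forward model.
#'
#' @param sim A [simulate_occlusion()] result.
#' @param instrument The [instrument_model()] providing noise levels.
#' @param seed Integer seed.
#' @return A channel data frame of the same shape.
#' @export
resample_noise <- function(sim, instrument, seed) {
  clean <- attr(sim, "noiseless")
  if (is.null(clean)) stop("simulation carries no noiseless cache")
  set.seed(seed)
  m <- nrow(clean)
  out <- clean
  out$ac <- clean$ac * (1 + stats::rnorm(m, 0, instrument$amp_noise_rel))
  out$phase_rad <- clean$phase_rad +
    stats::rnorm(m, 0, instrument$phase_noise_rad)
  out
}

#' Write a channel recording as CSV
#'
#' Values are rounded to 12 significant digits so that equal-seed runs are
#' byte-identical across platforms.
#'
#' @param channels Channel data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channels <- function(channels, path) {
  out <- channels
  out$ac <- signif(out$ac, 12)
  out$phase_rad <- signif(out$phase_rad, 12)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
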