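#' Configuration for the synthetic electrogastrogram generator
#'
#' The generator emulates the passive-viewing block design: one disgust and
#' one neutral block, recorded continuously at 200 Hz on four sensors.
#' Latent sources are a normogastric (3 cpm), a bradygastric (1 cpm) and a
#' tachygastric (6 cpm) oscillation, mixed across sensors, with per-sensor
#' drift, Gaussian noise and sparse single-sample spike artifacts. During
#' the disgust block the normogastric source amplitude is multiplied by
#' `(1 - attenuation_delta)`, so the disgust-to-neutral normogastric
#' peak-power ratio has ground truth `(1 - attenuation_delta)^2`.
#'
#' @param sampling_rate samples/s
#' @param n_sensors number of sensors
#' @param normo_freq,brady_freq,tachy_freq source frequencies, cycles/min
#' @param component_amplitudes amplitudes (normo, brady, tachy), arbitrary
#'   units; normogastric dominance mirrors real gastric spectra
#' @param mixing_matrix `n_sensors x 3` weights; must have full column rank
#' @param noise_sd per-sensor Gaussian noise SD (units); a free knob — the
#'   field has no calibrated noise-floor model
#' @param spike_rate single-sample artifact events per minute per sensor
#' @param spike_amplitude artifact magnitude (units, random sign)
#' @param drift_slope slow per-sensor drift, units/s
#' @param attenuation_delta normogastric attenuation during disgust, in
#'   `[0, 1)`
#' @param block_order `"disgust_first"` or `"neutral_first"`
#' @param block_duration seconds per block (~780 s matches a 28-trial block
#'   of 20 s presentations with jittered intervals)
#' @param freq_jitter if `TRUE`, source frequencies get +/-5% per-cycle
#'   jitter
#' @param seed RNG seed
#' @return an object of class `egg_sim_config`
#' @export
egg_sim_config <- function(sampling_rate = 200, n_sensors = 4,
                           normo_freq = 3, brady_freq = 1, tachy_freq = 6,
                           component_amplitudes = c(normo = 1, brady = 0.35,
                                                    tachy = 0.25),
                           mixing_matrix = NULL,
                           noise_sd = 0.1, spike_rate = 2,
                           spike_amplitude = 8, drift_slope = 0.005,
                           attenuation_delta = 0,
                           block_order = c("disgust_first", "neutral_first"),
                           block_duration = 780, freq_jitter = FALSE,
                           seed = 1) {
  block_order <- match.arg(block_order)
  if (sampling_rate <= 0) abort_input("sampling_rate must be > 0")
  if (block_duration <= 0) abort_input("block_duration must be > 0")
  if (attenuation_delta < 0 || attenuation_delta >= 1)
    abort_input("attenuation_delta must be in [0, 1)")
  if (is.null(mixing_matrix))
    mixing_matrix <- matrix(c(1.0, 0.5, 0.3,
                              0.8, 0.9, 0.2,
                              0.6, 0.4, 0.9,
                              0.9, 0.2, 0.6)[seq_len(3 * n_sensors)],
                            nrow = n_sensors, ncol = 3, byrow = TRUE)
  mixing_matrix <- as.matrix(mixing_matrix)
  if (nrow(mixing_matrix) != n_sensors || ncol(mixing_matrix) != 3)
    abort_input("mixing_matrix must be n_sensors x 3")
  if (qr(mixing_matrix)$rank < ncol(mixing_matrix))
    abort_input("mixing_matrix is rank deficient; source recovery would be ",
                "ill-posed")
  structure(list(sampling_rate = sampling_rate, n_sensors = n_sensors,
                 normo_freq = normo_freq, brady_freq = brady_freq,
                 tachy_freq = tachy_freq,
                 component_amplitudes = component_amplitudes,
                 mixing_matrix = mixing_matrix, noise_sd = noise_sd,
                 spike_rate = spike_rate, spike_amplitude = spike_amplitude,
                 drift_slope = drift_slope,
                 attenuation_delta = attenuation_delta,
                 block_order = block_order, block_duration = block_duration,
                 freq_jitter = freq_jitter, seed = seed),
            class = "egg_sim_config")
}

# instantaneous phase for a (possibly jittered) oscillation
source_phase <- function(freq_cpm, t, fs, jitter) {
  f_hz <- cpm_to_hz(freq_cpm)
  if (!jitter) return(2 * pi * f_hz * t)
  n_cycles <- ceiling(max(t) * f_hz) + 1
  fac <- rep(1 + runif(n_cycles, -0.05, 0.05), each = ceiling(1 / f_hz * fs))
  f_inst <- f_hz * fac[seq_along(t)]
  2 * pi * cumsum(f_inst) / fs
}

#' Generate a synthetic electrogastrogram with known ground truth
#'
#' @param cfg an [egg_sim_config()]
#' @param participant_id identifier
#' @return a list: `recording` (an [egg_recording()] spanning two blocks)
#'   and `ground_truth` (source frequencies/amplitudes, the attenuation
#'   delta, the mixing matrix, and the clean source time-series)
#' @export
generate_egg <- function(cfg, participant_id = "sim01") {
  stopifnot(inherits(cfg, "egg_sim_config"))
  fs <- cfg$sampling_rate
  n <- round(2 * cfg$block_duration * fs)
  t <- (seq_len(n) - 1) / fs
  amps <- cfg$component_amplitudes
  freqs <- c(cfg$normo_freq, cfg$brady_freq, cfg$tachy_freq)
  if (cfg$block_order == "disgust_first") {
    ev <- data.frame(label = c("block_disgust", "block_neutral"),
                     start_s = c(0, cfg$block_duration),
                     end_s = c(cfg$block_duration, 2 * cfg$block_duration))
  } else {
    ev <- data.frame(label = c("block_neutral", "block_disgust"),
                     start_s = c(0, cfg$block_duration),
                     end_s = c(cfg$block_duration, 2 * cfg$block_duration))
  }
  dis <- ev[ev$label == "block_disgust", ]
  in_disgust <- t >= dis$start_s & t < dis$end_s

  out <- with_seed(cfg$seed, {
    phases0 <- runif(3, 0, 2 * pi)
    S <- sapply(seq_len(3), function(k) {
      ph <- source_phase(freqs[k], t, fs, cfg$freq_jitter)
      a <- rep(unname(amps[k]), n)
      if (k == 1) a[in_disgust] <- a[in_disgust] * (1 - cfg$attenuation_delta)
      a * sin(ph + phases0[k])
    })
    X <- S %*% t(cfg$mixing_matrix)
    drift_fac <- rep_len(c(1, -1, 0.5, -0.5), cfg$n_sensors)
    for (j in seq_len(cfg$n_sensors)) {
      X[, j] <- X[, j] + cfg$drift_slope * drift_fac[j] * t
      if (cfg$noise_sd > 0) X[, j] <- X[, j] + rnorm(n, 0, cfg$noise_sd)
      if (cfg$spike_rate > 0) {
        n_sp <- rpois(1, cfg$spike_rate * 2 * cfg$block_duration / 60)
        if (n_sp > 0) {
          idx <- sample.int(n, n_sp)
          X[idx, j] <- X[idx, j] +
            sample(c(-1, 1), n_sp, replace = TRUE) * cfg$spike_amplitude
        }
      }
    }
    list(S = S, X = X)
  })
  colnames(out$X) <- paste0("ch", seq_len(cfg$n_sensors))
  rec <- egg_recording(out$X, fs, ev, participant_id)
  gt <- list(source_freqs_cpm = freqs,
             source_amplitudes = unname(amps),
             attenuation_delta = cfg$attenuation_delta,
             expected_peak_ratio = (1 - cfg$attenuation_delta)^2,
             mixing_matrix = cfg$mixing_matrix,
             block_order = cfg$block_order,
             sources = out$S, seed = cfg$seed)
  list(recording = rec, ground_truth = gt)
}
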