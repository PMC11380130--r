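# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# brute-force Hampel: literal per-window median/MAD definition
oracle_hampel <- function(x, window, threshold) {
  half <- window %/% 2
  out <- x
  n <- length(x)
  for (i in seq_len(n)) {
    k <- min(half, i - 1, n - i)
    w <- x[(i - k):(i + k)]
    m <- median(w)
    md <- median(abs(w - m))
    if (abs(x[i] - m) > threshold * 1.4826 * md) out[i] <- m
  }
  out
}

# Hann-windowed periodogram, written independently of hann_power
oracle_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  Y <- fft(x * w)
  nh <- n %/% 2 + 1
  p <- Mod(Y[1:nh])^2
  freq_cpm <- (0:(nh - 1)) / n * fs * 60
  list(freq_cpm = freq_cpm, power = p)   # unnormalised; use for ratios/argmax
}

# closed-form one-sided peak power of a Hann-windowed on-bin tone of
# amplitude A under the package's normalisation
oracle_tone_peak <- function(A, n) {
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  2 * (A * sum(w) / 2)^2 / (n * sum(w^2))
}

# a hand-built gaze trial from explicit fixations (for forced-sum dwell tests)
make_trial <- function(fixations, layout = aoi_layout(disgust_side = "left"),
                       n_samples = 12000, invalid_fraction = 0,
                       participant_id = "t01", trial_index = 1) {
  t_ms <- seq_len(n_samples) - 1
  valid <- rep(TRUE, n_samples)
  if (invalid_fraction > 0)
    valid[seq_len(round(invalid_fraction * n_samples))] <- FALSE
  x <- rep(mean(layout$left_span), n_samples)
  for (i in seq_len(nrow(fixations))) {
    sel <- t_ms >= fixations$start_ms[i] & t_ms < fixations$end_ms[i]
    x[sel] <- fixations$x[i]
  }
  x[!valid] <- NA
  structure(list(trial_index = trial_index, pair_id = 1L, presentation = 1L,
                 participant_id = participant_id,
                 samples = data.frame(t_ms = t_ms, x = x,
                                      y = rep(540, n_samples), valid = valid),
                 fixations = fixations, layout = layout),
            class = "gaze_trial")
}

# a quick small-but-valid EGG config for tests (shorter blocks than the
# ~780 s default purely for runtime; 300 s still gives 0.2 cpm resolution)
quick_egg_config <- function(..., block_duration = 300) {
  egg_sim_config(block_duration = block_duration, ...)
}

# a synthetic band-limited power_spectrum object for band-summary tests
flat_spectrum <- function(value, condition, df_cpm = 0.1, fmax = 12) {
  f <- seq(0, fmax, by = df_cpm)
  structure(list(freq_cpm = f, power = rep(value, length(f)),
                 condition = condition, n_sensors_averaged = 1L),
            class = "power_spectrum")
}
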