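#' Filtering parameters for the electrogastrogram pipeline
#'
#' Defaults follow the standard gastric preprocessing chain: a Hampel
#' despiking filter whose window spans one normogastric cycle (4000 samples
#' at 200 Hz) with a rejection threshold of 3 scaled MADs, and a zero-phase
#' Butterworth band-pass from 0.5 to 10 cycles/min (~8.3e-3 to ~0.17 Hz).
#'
#' @param hampel_window window size in samples; used as a centered window of
#'   `2 * floor(hampel_window / 2) + 1` samples, truncated symmetrically at
#'   the edges
#' @param hampel_threshold rejection threshold in multiples of
#'   1.4826 * MAD (Gaussian-consistent scaling)
#' @param bp_low,bp_high band-pass corner frequencies in cycles/min
#' @param bp_order Butterworth prototype order (the band-pass has twice as
#'   many poles); applied forward-backward, so the effective attenuation is
#'   squared and the phase response is zero
#' @return an object of class `filter_params`
#' @export
filter_params <- function(hampel_window = 4000, hampel_threshold = 3,
                          bp_low = 0.5, bp_high = 10, bp_order = 4) {
  if (hampel_window < 1) abort_input("hampel_window must be >= 1")
  if (hampel_threshold <= 0) abort_input("hampel_threshold must be > 0")
  if (!(bp_low > 0 && bp_low < bp_high))
    abort_input("need 0 < bp_low < bp_high (cycles/min)")
  if (bp_order < 1) abort_input("bp_order must be >= 1")
  structure(list(hampel_window = as.integer(hampel_window),
                 hampel_threshold = hampel_threshold,
                 bp_low = bp_low, bp_high = bp_high,
                 bp_order = as.integer(bp_order)),
            class = "filter_params")
}

#' Remove the mean from every channel of a recording
#'
#' @param recording an [egg_recording()] or a numeric vector/matrix
#' @return the same object with each channel shifted to mean zero
#' @export
demean <- function(recording) {
  if (inherits(recording, "egg_recording")) {
    recording$channels <- demean(recording$channels)
    return(recording)
  }
  x <- recording
  if (is.matrix(x)) {
    if (nrow(x) == 0) abort_input("cannot demean an empty channel")
    return(sweep(x, 2, colMeans(x)))
  }
  if (length(x) == 0) abort_input("cannot demean an empty channel")
  x - mean(x)
}

#' Hampel despiking filter
#'
#' Each sample is compared with the median of its centered window; samples
#' deviating by more than `threshold * 1.4826 * MAD` of that window are
#' replaced by the window median. Edge windows are truncated symmetrically so
#' every window stays centered and odd-sized. Semantics match the brute-force
#' per-window median/MAD definition exactly.
#'
#' @param x numeric vector (one channel)
#' @param window window size in samples (a `filter_params` object is also
#'   accepted)
#' @param threshold rejection threshold in scaled-MAD multiples
#' @return the despiked channel
#' @export
hampel <- function(x, window = 4000, threshold = 3) {
  if (inherits(window, "filter_params")) {
    threshold <- window$hampel_threshold
    window <- window$hampel_window
  }
  if (!is.numeric(x) || length(x) == 0) abort_input("x must be non-empty numeric")
  if (window > length(x))
    abort_input("hampel window (", window, ") longer than signal (",
                length(x), ")")
  .hampel_cpp(as.numeric(x), as.integer(window), threshold)
}

# --- Butterworth band-pass design (second-order sections) -----------------

# Analog Butterworth prototype poles (unit cutoff), order n
butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Design a digital Butterworth band-pass as second-order sections.
# f_low/f_high in Hz, fs in Hz. Returns list(sos = ns x 6 matrix).
butter_bandpass_sos <- function(f_low, f_high, fs, order = 4) {
  nyq <- fs / 2
  if (!(f_low > 0 && f_low < f_high && f_high < nyq))
    abort_input("cutoffs must satisfy 0 < low < high < Nyquist (",
                signif(nyq, 4), " Hz)")
  fs2 <- 2 * fs
  # bilinear pre-warp
  w1 <- fs2 * tan(pi * f_low / fs)
  w2 <- fs2 * tan(pi * f_high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  p <- butter_prototype(order)
  # low-pass -> band-pass: each pole splits into two
  pb <- p * bw / 2
  disc <- sqrt(pb^2 - w0^2)
  poles_a <- c(pb + disc, pb - disc)          # 2*order analog poles
  zeros_a <- rep(0 + 0i, order)               # order zeros at s = 0
  gain_a <- bw^order
  # bilinear transform
  poles_z <- (fs2 + poles_a) / (fs2 - poles_a)
  gain_z <- gain_a * Re(prod(fs2 - zeros_a) / prod(fs2 - poles_a))
  # digital zeros: 'order' at z = +1 (from s = 0) and 'order' at z = -1
  # pair conjugate poles; each section gets one zero at +1 and one at -1,
  # i.e. numerator (z-1)(z+1) -> b = g * c(1, 0, -1)
  pos <- poles_z[Im(poles_z) > 0]
  pos <- pos[order(-Mod(pos))]                # pair by pole radius
  ns <- length(pos)
  g_sec <- abs(gain_z)^(1 / ns)
  sos <- matrix(0, ns, 6)
  for (s in seq_len(ns)) {
    pk <- pos[s]
    sos[s, ] <- c(g_sec, 0, -g_sec, 1, -2 * Re(pk), Mod(pk)^2)
  }
  if (gain_z < 0) sos[1, 1:3] <- -sos[1, 1:3]
  list(sos = sos, f_low = f_low, f_high = f_high, fs = fs, order = order)
}

# complex frequency response of an SOS cascade at frequencies f (Hz)
sos_freq_response <- function(design, f) {
  z <- exp(-2i * pi * f / design$fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(design$sos))) {
    b <- design$sos[s, 1:3]; a <- design$sos[s, 4:6]
    h <- h * (b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2)
  }
  h
}

# steady-state initial conditions for one biquad (response to unit step)
biquad_zi <- function(b, a) {
  # transposed DF2: y = b0 x + z1; z1' = b1 x - a1 y + z2; z2' = b2 x - a2 y
  y1 <- sum(b) / sum(a)   # H(1)
  z2 <- b[3] - a[3] * y1
  z1 <- b[2] - a[2] * y1 + z2
  c(z1, z2)
}

sosfilt <- function(x, sos, x0 = x[1]) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2)
  # propagate the scaling of the step response through the cascade
  scale <- x0
  for (s in seq_len(ns)) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    zi[s, ] <- biquad_zi(b, a) * scale
    scale <- scale * sum(b) / sum(a)
  }
  .sosfilt_cpp(as.numeric(x), sos, zi)
}

#' Zero-phase Butterworth band-pass in cycles/min
#'
#' Designs a Butterworth band-pass (as numerically robust second-order
#' sections) with corners given in cycles/min and applies it
#' forward-backward, so the output has zero phase shift — important for the
#' slow gastric phase. Edges are padded by odd reflection with steady-state
#' section initial conditions; residual edge transients should be trimmed by
#' the caller when amplitudes matter.
#'
#' @param x numeric vector (one channel)
#' @param sampling_rate samples per second
#' @param params a [filter_params()] object (corners/order in cycles/min)
#' @return the filtered channel
#' @export
bandpass <- function(x, sampling_rate, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  design <- butter_bandpass_sos(cpm_to_hz(params$bp_low),
                                cpm_to_hz(params$bp_high),
                                sampling_rate, params$bp_order)
  n <- length(x)
  if (n < 10) abort_input("signal too short to band-pass filter")
  npad <- min(n - 1, 5000L)
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  ext <- c(left, x, right)
  y <- sosfilt(ext, design$sos)
  y <- rev(sosfilt(rev(y), design$sos))
  y[(npad + 1):(npad + n)]
}
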