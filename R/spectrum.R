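# One-sided Hann-windowed power spectrum.
# Normalisation: sum(power over all one-sided bins) equals
# mean(windowed^2) / mean(window^2), i.e. the window-compensated mean square
# of the segment (a Parseval identity the tests assert).
hann_power <- function(x, sampling_rate) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
  y <- x * w
  Y <- fft(y)
  nh <- n %/% 2 + 1L
  p <- Mod(Y[seq_len(nh)])^2 / (n * sum(w^2))
  # fold negative frequencies onto positive bins (DC and Nyquist unpaired)
  mult <- rep(2, nh)
  mult[1] <- 1
  if (n %% 2 == 0) mult[nh] <- 1
  p <- p * mult
  freq_cpm <- (seq_len(nh) - 1) / n * sampling_rate * 60
  list(freq_cpm = freq_cpm, power = p)
}

#' Per-block power spectrum of a cleaned recording
#'
#' For each sensor, the samples of the requested condition block are
#' Hann-windowed and Fourier transformed; the resulting power spectra are
#' averaged over sensors. Frequencies are reported in cycles/min.
#'
#' @param recording an [egg_recording()] (typically the reconstructed,
#'   artifact-screened signal)
#' @param condition `"disgust"` or `"neutral"`
#' @return an object of class `power_spectrum` with fields `freq_cpm`,
#'   `power`, `condition`, `n_sensors_averaged`
#' @export
block_spectrum <- function(recording, condition = c("disgust", "neutral")) {
  condition <- match.arg(condition)
  iv <- block_interval(recording, condition)
  fs <- recording$sampling_rate
  i0 <- floor(iv[1] * fs) + 1
  i1 <- min(nrow(recording$channels), ceiling(iv[2] * fs))
  n <- i1 - i0 + 1
  min_n <- ceiling(2 * cycle_samples(3, fs))  # two normogastric cycles
  if (n < min_n)
    abort_input("block too short for spectral analysis: ", n,
                " samples, need >= ", min_n, " (two normogastric cycles)")
  seg <- recording$channels[i0:i1, , drop = FALSE]
  specs <- apply(seg, 2, hann_power, sampling_rate = fs, simplify = FALSE)
  power <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
  structure(list(freq_cpm = specs[[1]]$freq_cpm, power = power,
                 condition = condition,
                 n_sensors_averaged = ncol(seg)),
            class = "power_spectrum")
}

#' Gastric frequency bands in cycles/min
#'
#' The conventional bands: bradygastric 0.5-2, normogastric 2-4,
#' tachygastric 4-10 cycles/min. A bin at exactly 2 or 4 cpm belongs to the
#' normogastric band (closed normo band, open neighbours).
#'
#' @param brady_low lower edge of the bradygastric band; 0.5 matches the
#'   band-pass high-pass corner (an alternative convention uses 0.1)
#' @return named list of `c(low, high)` band edges
#' @export
gastric_bands <- function(brady_low = 0.5) {
  list(brady = c(brady_low, 2), normo = c(2, 4), tachy = c(4, 10))
}

band_mask <- function(freq, band, edges) {
  switch(band,
    brady = freq >= edges$brady[1] & freq < edges$brady[2],
    normo = freq >= edges$normo[1] & freq <= edges$normo[2],
    tachy = freq > edges$tachy[1] & freq <= edges$tachy[2])
}

#' Band-power summary of a disgust and a neutral block spectrum
#'
#' Reduces the two per-condition spectra to mean, SD, maximum, and
#' proportion of power per gastric band, plus the normogastric peak power
#' per condition. Proportions are relative to total power over the full
#' analysed range (brady low edge to 10 cpm) and sum to 1 per condition.
#'
#' @param spec_disgust,spec_neutral `power_spectrum` objects sharing a
#'   frequency grid
#' @param bands band edges from [gastric_bands()]
#' @return an object of class `band_power_summary`: a data.frame with
#'   columns `condition`, `band`, `mean`, `sd`, `max`, `proportion`, and an
#'   attribute `normo_peak` (named numeric, one value per condition). An
#'   all-zero spectrum yields `NA` proportions and a `flagged_missing`
#'   attribute rather than NaN propagation.
#' @export
band_summary <- function(spec_disgust, spec_neutral, bands = gastric_bands()) {
  stopifnot(inherits(spec_disgust, "power_spectrum"),
            inherits(spec_neutral, "power_spectrum"))
  if (length(spec_disgust$freq_cpm) != length(spec_neutral$freq_cpm) ||
      max(abs(spec_disgust$freq_cpm - spec_neutral$freq_cpm)) > 1e-9)
    abort_input("spectra must share a frequency grid")
  specs <- list(disgust = spec_disgust, neutral = spec_neutral)
  rows <- list(); peaks <- c(disgust = NA_real_, neutral = NA_real_)
  flagged <- character(0)
  for (cond in names(specs)) {
    f <- specs[[cond]]$freq_cpm; p <- specs[[cond]]$power
    total_mask <- f >= bands$brady[1] & f <= bands$tachy[2]
    total <- sum(p[total_mask])
    if (total <= 0) flagged <- c(flagged, cond)
    for (b in names(bands)) {
      m <- band_mask(f, b, bands)
      pb <- p[m]
      rows[[paste(cond, b)]] <- data.frame(
        condition = cond, band = b,
        mean = mean(pb), sd = sd(pb), max = max(pb),
        proportion = if (total > 0) sum(pb) / total else NA_real_)
    }
    nm <- band_mask(f, "normo", bands)
    peaks[cond] <- max(p[nm])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("band_power_summary", "data.frame"),
            normo_peak = peaks,
            flagged_missing = if (length(flagged)) flagged else NULL)
}

#' @export
print.band_power_summary <- function(x, ...) {
  cat("<band_power_summary>\n")
  print.data.frame(x, digits = 4)
  pk <- attr(x, "normo_peak")
  cat(sprintf("normo_peak: disgust %.4g, neutral %.4g\n",
              pk["disgust"], pk["neutral"]))
  if (!is.null(attr(x, "flagged_missing")))
    cat("flagged missing:", attr(x, "flagged_missing"), "\n")
  invisible(x)
}

#' Gastric disgust index
#'
#' The log of the ratio of normogastric peak power during the disgust block
#' to that during the neutral block. Negative values indicate normogastric
#' attenuation under disgust ("proto-nausea").
#'
#' @param summary a [band_summary()] result
#' @return a dimensionless score; `NA` (with a warning) when either peak is
#'   non-positive or the spectra were flagged missing
#' @export
gastric_disgust_index <- function(summary) {
  stopifnot(inherits(summary, "band_power_summary"))
  pk <- attr(summary, "normo_peak")
  if (!is.null(attr(summary, "flagged_missing")) ||
      any(!is.finite(pk)) || any(pk <= 0)) {
    warning("non-positive normogastric peak; index flagged missing")
    return(NA_real_)
  }
  log(pk[["disgust"]] / pk[["neutral"]])
}

#' Normogastric signal-to-noise ratio of a component
#'
#' Peak power in the normogastric range (2-4 cpm) divided by the mean power
#' over the remaining analysed frequencies. The denominator is restricted to
#' the band-pass range (default 0.5-10 cpm): frequencies the filter removed
#' would deflate it artificially. Uses the same Hann/FFT estimator as
#' [block_spectrum()], over the whole series.
#'
#' @param source numeric vector (one unmixed component)
#' @param sampling_rate samples per second
#' @param normo normogastric range, cycles/min (closed)
#' @param analysed analysed range, cycles/min
#' @return a dimensionless ratio; `Inf` (with a warning) when all analysed
#'   out-of-band power is zero
#' @export
component_snr <- function(source, sampling_rate, normo = c(2, 4),
                          analysed = c(0.5, 10)) {
  n <- length(source)
  if (n < 2 * cycle_samples(3, sampling_rate))
    abort_input("source too short for a stable SNR estimate")
  sp <- hann_power(source, sampling_rate)
  f <- sp$freq_cpm
  in_norm <- f >= normo[1] & f <= normo[2]
  in_rest <- f >= analysed[1] & f <= analysed[2] & !in_norm
  if (!any(in_norm) || !any(in_rest))
    abort_input("frequency grid too coarse to resolve the normogastric band")
  num <- max(sp$power[in_norm])
  den <- mean(sp$power[in_rest])
  if (den == 0) {
    warning("zero out-of-band power; SNR is +Inf")
    return(Inf)
  }
  num / den
}
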