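# FastICA, deflation scheme with the logcosh negentropy contrast.
# Whitening first (eigendecomposition of the channel covariance), seeded
# random orthogonal initialisation, max 500 iterations, tolerance 1e-4.
# Written here because the pipeline's component-screening contract depends
# on exact control over seeding, convergence reporting and reconstruction.
fastica_deflation <- function(X, n_components, seed = 0, max_iter = 500,
                              tol = 1e-4, alpha = 1) {
  n <- nrow(X); p <- ncol(X)
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  d <- eg$values[seq_len(n_components)]
  if (any(d < .Machine$double.eps * max(eg$values) * p))
    abort_input("channel covariance is rank deficient; cannot whiten")
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  K <- E %*% diag(1 / sqrt(d), n_components)
  Z <- Xc %*% K                             # n x k, whitened
  W <- matrix(0, n_components, n_components)
  converged <- logical(n_components)
  with_seed(seed, {
    for (comp in seq_len(n_components)) {
      w <- rnorm(n_components)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wx <- drop(Z %*% w)
        g <- tanh(alpha * wx)
        gp <- alpha * (1 - g^2)
        w_new <- colMeans(Z * g) - mean(gp) * w
        # Gram-Schmidt against previously extracted components
        if (comp > 1) {
          prev <- W[seq_len(comp - 1), , drop = FALSE]
          w_new <- w_new - drop(t(prev) %*% (prev %*% w_new))
        }
        w_new <- w_new / sqrt(sum(w_new^2))
        delta <- abs(abs(sum(w_new * w)) - 1)
        w <- w_new
        if (delta < tol) { converged[comp] <- TRUE; break }
      }
      W[comp, ] <- w
    }
  })
  S <- Z %*% t(W)                           # n x k sources (unit variance)
  A <- E %*% diag(sqrt(d), n_components) %*% t(W)  # p x k mixing
  list(S = S, A = A, K = K, W = W, means = means, converged = converged)
}

#' Decompose a recording into independent components
#'
#' Blind source separation of the preprocessed multi-channel
#' electrogastrogram (FastICA: whitening, then negentropy maximisation by
#' deflation), plus the normogastric signal-to-noise ratio of every
#' component. The decomposition is exactly invertible when all components
#' are kept.
#'
#' @param recording an [egg_recording()] (after [demean()], [hampel()],
#'   [bandpass()])
#' @param n_components number of components (default: one per sensor)
#' @param seed RNG seed for the component initialisation
#' @param max_iter,tol FastICA iteration controls
#' @return an object of class `component_decomposition` with fields
#'   `sources` (samples x components), `mixing` (sensors x components),
#'   `snr`, `kept` (filled by [select_and_reconstruct()]), `converged`,
#'   `seed`
#' @export
decompose <- function(recording, n_components = NULL, seed = 0,
                      max_iter = 500, tol = 1e-4) {
  stopifnot(inherits(recording, "egg_recording"))
  X <- recording$channels
  if (!all(is.finite(X))) abort_input("recording contains non-finite values")
  n_components <- n_components %||% ncol(X)
  if (n_components > ncol(X))
    abort_input("n_components exceeds the number of sensors")
  dec <- fastica_deflation(X, n_components, seed = seed,
                           max_iter = max_iter, tol = tol)
  if (!all(dec$converged))
    warning("ICA did not converge for component(s) ",
            paste(which(!dec$converged), collapse = ", "),
            " within the iteration budget; results flagged")
  snr <- apply(dec$S, 2, component_snr,
               sampling_rate = recording$sampling_rate)
  structure(list(sources = dec$S, mixing = dec$A, means = dec$means,
                 snr = snr, kept = integer(0), converged = dec$converged,
                 seed = seed, recording = recording),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat(sprintf("<component_decomposition> %d components, SNR: %s\n",
              ncol(x$sources), paste(signif(x$snr, 3), collapse = ", ")))
  if (length(x$kept)) cat("kept:", x$kept, "\n")
  invisible(x)
}

#' Screen components by normogastric SNR and reconstruct the recording
#'
#' Components with a signal-to-noise ratio under `threshold` are discarded
#' (a component at exactly the threshold is kept); the electrogastrogram is
#' reconstituted for all sensors by inverse-transforming the remaining
#' components. When no component survives, the participant is excluded for
#' gastric measures.
#'
#' @param dec a [decompose()] result
#' @param threshold SNR threshold (default 3)
#' @return a list: `excluded` (logical), `kept` (component indices), and —
#'   unless excluded — `recording`, the reconstructed [egg_recording()]
#' @export
select_and_reconstruct <- function(dec, threshold = 3) {
  stopifnot(inherits(dec, "component_decomposition"))
  kept <- which(dec$snr >= threshold)
  if (length(kept) == 0)
    return(list(excluded = TRUE, kept = integer(0), recording = NULL))
  Xh <- dec$sources[, kept, drop = FALSE] %*%
    t(dec$mixing[, kept, drop = FALSE])
  Xh <- sweep(Xh, 2, dec$means, `+`)
  rec <- dec$recording
  colnames(Xh) <- colnames(rec$channels)
  rec$channels <- Xh
  list(excluded = FALSE, kept = kept, recording = rec)
}

#' Run the full electrogastrogram data-reduction chain
#'
#' Stage order is fixed: demean, Hampel despiking, zero-phase Butterworth
#' band-pass (0.5-10 cpm), ICA, component screening by normogastric SNR,
#' reconstruction, per-block Hann/FFT spectra, band-power summary, and the
#' gastric disgust index.
#'
#' @param recording an [egg_recording()]
#' @param params [filter_params()]
#' @param snr_threshold component-screening threshold
#' @param seed ICA seed
#' @param bands [gastric_bands()]
#' @return a list with `excluded`, `kept`, `snr`, `spectra` (disgust and
#'   neutral `power_spectrum`), `summary` (a [band_summary()]), and `index`
#'   (the gastric disgust index); when the participant is excluded only the
#'   first three fields are populated
#' @export
run_egg_pipeline <- function(recording, params = filter_params(),
                             snr_threshold = 3, seed = 0,
                             bands = gastric_bands()) {
  rec <- demean(recording)
  fs <- rec$sampling_rate
  rec$channels <- apply(rec$channels, 2, hampel,
                        window = params$hampel_window,
                        threshold = params$hampel_threshold)
  rec$channels <- apply(rec$channels, 2, bandpass,
                        sampling_rate = fs, params = params)
  dec <- decompose(rec, seed = seed)
  sel <- select_and_reconstruct(dec, threshold = snr_threshold)
  if (sel$excluded)
    return(list(excluded = TRUE, kept = integer(0), snr = dec$snr,
                participant_id = recording$participant_id))
  sd_ <- block_spectrum(sel$recording, "disgust")
  sn_ <- block_spectrum(sel$recording, "neutral")
  summ <- band_summary(sd_, sn_, bands = bands)
  idx <- gastric_disgust_index(summ)
  list(excluded = FALSE, kept = sel$kept, snr = dec$snr,
       spectra = list(disgust = sd_, neutral = sn_),
       summary = summ, index = idx,
       participant_id = recording$participant_id)
}
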