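#' Convert gastric frequencies between cycles/min and Hz
#'
#' Gastric rhythms are conventionally reported in cycles per minute (cpm);
#' 3 cpm (the normogastric typical frequency) is 0.05 Hz.
#'
#' @param cpm frequency in cycles per minute
#' @param hz frequency in Hz
#' @return the converted frequency
#' @examples
#' cpm_to_hz(3)   # 0.05
#' hz_to_cpm(0.05)
#' @export
cpm_to_hz <- function(cpm) cpm / 60

#' @rdname cpm_to_hz
#' @export
hz_to_cpm <- function(hz) hz * 60

#' Number of samples in one cycle of a rhythm
#'
#' @param freq_cpm rhythm frequency in cycles/min
#' @param sampling_rate samples per second
#' @return samples per cycle (e.g. one 3 cpm cycle at 200 Hz spans 4000
#'   samples)
#' @export
cycle_samples <- function(freq_cpm, sampling_rate) {
  stopifnot(freq_cpm > 0, sampling_rate > 0)
  sampling_rate * 60 / freq_cpm
}

# run expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(...) stop(..., call. = FALSE)
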