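#' Multi-channel electrogastrogram recording
#'
#' The canonical in-memory container for a gastric recording: a samples x
#' sensors numeric matrix at a fixed sampling rate, plus condition-block
#' event annotations. The two condition blocks (`block_disgust`,
#' `block_neutral`) must lie within the recording and must not overlap;
#' additional event labels (e.g. artifact spans) are carried along untouched.
#'
#' @param channels numeric matrix, one column per sensor (columns are named
#'   `ch1..chK` if unnamed)
#' @param sampling_rate samples per second
#' @param events data.frame with columns `label`, `start_s`, `end_s`
#' @param participant_id identifier string
#' @return an object of class `egg_recording`
#' @export
egg_recording <- function(channels, sampling_rate, events,
                          participant_id = "p01") {
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  if (is.null(colnames(channels)))
    colnames(channels) <- paste0("ch", seq_len(ncol(channels)))
  if (sampling_rate <= 0) abort_input("sampling_rate must be > 0")
  events <- as.data.frame(events)
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(events)))
    abort_input("events must have columns label, start_s, end_s")
  dur <- nrow(channels) / sampling_rate
  blocks <- events[events$label %in% c("block_disgust", "block_neutral"), ]
  if (nrow(blocks) < 2)
    abort_input("events must contain both block_disgust and block_neutral")
  if (any(events$start_s < 0) || any(events$end_s > dur + 1e-9) ||
      any(events$end_s <= events$start_s))
    abort_input("event intervals must lie within the recording")
  b <- blocks[order(blocks$start_s), ]
  if (b$end_s[1] > b$start_s[2] + 1e-9)
    abort_input("disgust and neutral block intervals overlap")
  structure(list(channels = channels,
                 sampling_rate = sampling_rate,
                 events = events,
                 participant_id = as.character(participant_id)),
            class = "egg_recording")
}

#' @export
print.egg_recording <- function(x, ...) {
  cat(sprintf("<egg_recording> %s: %d samples x %d sensors @ %g Hz (%.1f s)\n",
              x$participant_id, nrow(x$channels), ncol(x$channels),
              x$sampling_rate, nrow(x$channels) / x$sampling_rate))
  for (i in seq_len(nrow(x$events)))
    cat(sprintf("  %-14s %8.1f - %8.1f s\n", x$events$label[i],
                x$events$start_s[i], x$events$end_s[i]))
  invisible(x)
}

block_interval <- function(recording, condition = c("disgust", "neutral")) {
  condition <- match.arg(condition)
  lab <- paste0("block_", condition)
  ev <- recording$events[recording$events$label == lab, ]
  if (nrow(ev) != 1) abort_input("expected exactly one ", lab, " event")
  c(ev$start_s, ev$end_s)
}
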