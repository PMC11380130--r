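# On-disk formats are vendor-neutral delimited text:
#   EGG:    <stem>.csv          t_s, ch1..chK
#           <stem>_events.csv   label, start_s, end_s
#   gaze:   <stem>_samples.csv  trial_index, pair_id, presentation,
#                               disgust_side, t_ms, x, y, valid
#           <stem>_fixations.csv (optional) trial_index, start_ms, end_ms, x, y
#   AOI layout and configs: JSON (YAML also read when the yaml package is
#   available).
# Readers reject invariant-violating files; they never repair them.

#' Write / read an electrogastrogram recording
#'
#' The samples file holds `t_s` and one column per sensor; events live in a
#' sibling `<stem>_events.csv`. Round trips are lossless to full double
#' precision.
#'
#' @param recording an [egg_recording()]
#' @param stem path stem (files `<stem>.csv` and `<stem>_events.csv`)
#' @return `write_egg` returns the stem invisibly; `read_egg` returns an
#'   [egg_recording()]
#' @export
write_egg <- function(recording, stem) {
  stopifnot(inherits(recording, "egg_recording"))
  n <- nrow(recording$channels)
  dt <- data.table::data.table(
    t_s = (seq_len(n) - 1) / recording$sampling_rate)
  for (j in colnames(recording$channels))
    dt[[j]] <- recording$channels[, j]
  data.table::fwrite(dt, paste0(stem, ".csv"))
  data.table::fwrite(recording$events, paste0(stem, "_events.csv"))
  invisible(stem)
}

#' @rdname write_egg
#' @param participant_id identifier attached to the loaded recording
#' @export
read_egg <- function(stem, participant_id = basename(stem)) {
  f <- paste0(stem, ".csv"); fe <- paste0(stem, "_events.csv")
  for (p in c(f, fe)) if (!file.exists(p)) abort_input("no such file: ", p)
  # ragged rows only warn in fread; record the warning and abort *after*
  # fread has finished (aborting from inside the handler would longjmp out
  # of fread's C parser and leave its internal state dirty)
  ragged_msg <- NULL
  dt <- withCallingHandlers(
    tryCatch(data.table::fread(f, fill = FALSE),
             error = function(e)
               abort_input("unparseable EGG file ", f, ": ",
                           conditionMessage(e))),
    warning = function(w) {
      ragged_msg <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (!is.null(ragged_msg))
    abort_input("unparseable EGG file ", f, ": ", ragged_msg)
  if (!"t_s" %in% names(dt) || ncol(dt) < 2)
    abort_input(f, ": expected columns t_s, ch1..chK")
  chn <- setdiff(names(dt), "t_s")
  bad <- which(!vapply(dt[, chn, with = FALSE], is.numeric, logical(1)))
  if (length(bad))
    abort_input(f, ": non-numeric channel column '", chn[bad[1]], "'")
  t_s <- dt$t_s
  if (nrow(dt) < 2 || is.unsorted(t_s, strictly = TRUE))
    abort_input(f, ": time stamps must be strictly increasing")
  fs <- 1 / median(diff(t_s))
  ev <- data.table::fread(fe)
  egg_recording(as.matrix(dt[, chn, with = FALSE]), fs, as.data.frame(ev),
                participant_id)
}

#' Write / read preferential-looking gaze trials
#'
#' All trials go to a single long samples file; ground-truth or detected
#' fixations go to an optional sibling file. When the fixation file is
#' absent, trials load with an empty fixation table and downstream code
#' detects fixations itself.
#'
#' @param trials list of `gaze_trial` objects
#' @param stem path stem
#' @param write_fixations also write `<stem>_fixations.csv`
#' @return `write_gaze` returns the stem invisibly; `read_gaze` a list of
#'   `gaze_trial`
#' @export
write_gaze <- function(trials, stem, write_fixations = TRUE) {
  smp <- data.table::rbindlist(lapply(trials, function(tr) {
    cbind(data.table::data.table(trial_index = tr$trial_index,
                                 pair_id = tr$pair_id,
                                 presentation = tr$presentation,
                                 disgust_side = tr$layout$disgust_side),
          tr$samples)
  }))
  data.table::fwrite(smp, paste0(stem, "_samples.csv"))
  if (write_fixations) {
    fx <- data.table::rbindlist(lapply(trials, function(tr) {
      if (is.null(tr$fixations) || nrow(tr$fixations) == 0) return(NULL)
      cbind(data.table::data.table(trial_index = tr$trial_index),
            tr$fixations)
    }))
    data.table::fwrite(fx, paste0(stem, "_fixations.csv"))
  }
  invisible(stem)
}

#' @rdname write_gaze
#' @param layout an [aoi_layout()]; each trial's `disgust_side` is taken
#'   from the samples file
#' @param participant_id identifier attached to the loaded trials
#' @export
read_gaze <- function(stem, layout, participant_id = basename(stem)) {
  stopifnot(inherits(layout, "aoi_layout"))
  f <- paste0(stem, "_samples.csv")
  if (!file.exists(f)) abort_input("no such file: ", f)
  smp <- data.table::fread(f)
  need <- c("trial_index", "t_ms", "x", "y", "valid")
  if (!all(need %in% names(smp)))
    abort_input(f, ": expected columns ", paste(need, collapse = ", "))
  ff <- paste0(stem, "_fixations.csv")
  fx <- if (file.exists(ff)) data.table::fread(ff) else NULL
  lapply(split(smp, by = "trial_index", sorted = TRUE), function(d) {
    if (is.unsorted(d$t_ms, strictly = TRUE))
      abort_input(f, ": non-monotone timestamps in trial ", d$trial_index[1])
    lay <- layout
    if ("disgust_side" %in% names(d)) lay$disgust_side <- d$disgust_side[1]
    fixs <- if (!is.null(fx)) {
      fi <- fx[fx$trial_index == d$trial_index[1], ]
      as.data.frame(fi[, c("start_ms", "end_ms", "x", "y")])
    } else {
      data.frame(start_ms = numeric(0), end_ms = numeric(0),
                 x = numeric(0), y = numeric(0))
    }
    structure(list(trial_index = d$trial_index[1],
                   pair_id = if ("pair_id" %in% names(d)) d$pair_id[1] else NA,
                   presentation = if ("presentation" %in% names(d))
                     d$presentation[1] else NA,
                   participant_id = participant_id,
                   samples = as.data.frame(d[, c("t_ms", "x", "y", "valid")]),
                   fixations = fixs, layout = lay),
              class = "gaze_trial")
  })
}

#' Write / read an AOI layout as JSON
#'
#' @param layout an [aoi_layout()]
#' @param path JSON file path
#' @return `read_aoi` returns an [aoi_layout()]
#' @export
write_aoi <- function(layout, path) {
  stopifnot(inherits(layout, "aoi_layout"))
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aoi
#' @export
read_aoi <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  aoi_layout(left_span = raw$left_span, right_span = raw$right_span,
             disgust_side = raw$disgust_side,
             screen_width = raw$screen_width %||% 1920,
             screen_height = raw$screen_height %||% 1080)
}

#' Read a configuration file (JSON, or YAML when available)
#'
#' @param path config path; format chosen by extension
#' @return a named list
#' @export
read_config <- function(path) {
  if (grepl("\\.(ya?ml)$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort_input("YAML config requires the 'yaml' package; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write / read a delimited table (cohort tables, questionnaire responses,
#' derived results)
#'
#' Thin wrappers with stable column handling used by the CLI.
#'
#' @param x data.frame
#' @param path CSV path
#' @return `read_table_csv` returns a data.frame
#' @export
write_table_csv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) abort_input("no such file: ", path)
  as.data.frame(data.table::fread(path))
}
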