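#' Velocity-threshold fixation detection
#'
#' A documented substitute for proprietary tracker algorithms: point-to-point
#' speed is estimated with a central difference over +/-2 samples; contiguous
#' runs of valid samples below `velocity_threshold` lasting at least
#' `min_duration_ms` become fixations at the run's centroid. Blinks (invalid
#' samples) break runs.
#'
#' @param samples data.frame with `t_ms`, `x`, `y`, `valid`
#' @param velocity_threshold speed threshold in px/ms
#' @param min_duration_ms minimum fixation duration
#' @return data.frame of fixations (`start_ms`, `end_ms`, `x`, `y`); empty
#'   for an empty stream
#' @export
detect_fixations <- function(samples, velocity_threshold = 2,
                             min_duration_ms = 50) {
  if (nrow(samples) == 0)
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      x = numeric(0), y = numeric(0)))
  if (is.unsorted(samples$t_ms, strictly = TRUE))
    abort_input("sample timestamps must be strictly increasing")
  n <- nrow(samples)
  t <- samples$t_ms; x <- samples$x; y <- samples$y
  lag <- pmin(seq_len(n) + 2, n); lead <- pmax(seq_len(n) - 2, 1)
  dt <- t[lag] - t[lead]
  v <- sqrt((x[lag] - x[lead])^2 + (y[lag] - y[lead])^2) / pmax(dt, 1e-9)
  slow <- samples$valid & !is.na(v) & v < velocity_threshold
  r <- rle(slow)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  fix <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    dur <- t[i1] - t[i0]
    if (dur < min_duration_ms) return(NULL)
    data.frame(start_ms = t[i0], end_ms = t[i1],
               x = mean(x[i0:i1]), y = mean(y[i0:i1]))
  })
  fix <- do.call(rbind, fix)
  if (is.null(fix))
    fix <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      x = numeric(0), y = numeric(0))
  fix
}

in_span <- function(x, span) !is.na(x) & x >= span[1] & x < span[2]

#' Dwell times of one preferential-looking trial
#'
#' A fixation is assigned to an area of interest iff its x centroid lies in
#' that AOI's half-open horizontal span, regardless of y (the vertical gate
#' can be enabled via `use_y`). Dwell per stimulus is the summed duration of
#' assigned fixations; time in neither AOI is "other". The missing fraction
#' counts invalid samples over the stimulus window. A sample-count mode is
#' provided for sensitivity analyses.
#'
#' @param trial a `gaze_trial`; if it carries no fixations they are detected
#'   with [detect_fixations()]
#' @param mode `"fixations"` (primary) or `"samples"`
#' @param use_y also require the fixation centroid's y to lie on screen
#'   within the stimulus rows (off by default; the field rule is
#'   horizontal-span only)
#' @return a `dwell_result`: one-row data.frame with `trial_index`,
#'   `pair_id`, `presentation`, `participant_id`, `dwell_disgust_ms`,
#'   `dwell_neutral_ms`, `dwell_other_ms`, `missing_fraction`, `excluded`
#' @export
dwell <- function(trial, mode = c("fixations", "samples"), use_y = FALSE) {
  mode <- match.arg(mode)
  if (is.null(trial$layout)) abort_input("trial has no AOI layout")
  lay <- trial$layout
  dsp <- disgust_span(lay); nsp <- neutral_span(lay)
  smp <- trial$samples
  missing_fraction <- mean(!smp$valid)
  if (mode == "fixations") {
    fix <- trial$fixations
    if (is.null(fix) || nrow(fix) == 0) fix <- detect_fixations(smp)
    dur <- fix$end_ms - fix$start_ms
    ok_y <- if (use_y) fix$y >= 0 & fix$y <= lay$screen_height else TRUE
    d <- sum(dur[in_span(fix$x, dsp) & ok_y])
    nn <- sum(dur[in_span(fix$x, nsp) & ok_y])
    oth <- sum(dur) - d - nn
  } else {
    step <- if (nrow(smp) > 1) diff(smp$t_ms[1:2]) else 1
    v <- smp$valid
    d <- sum(in_span(smp$x, dsp) & v) * step
    nn <- sum(in_span(smp$x, nsp) & v) * step
    oth <- sum(v) * step - d - nn
  }
  structure(data.frame(trial_index = trial$trial_index %||% NA_integer_,
                       pair_id = trial$pair_id %||% NA_integer_,
                       presentation = trial$presentation %||% NA_integer_,
                       participant_id = trial$participant_id %||% NA_character_,
                       dwell_disgust_ms = d, dwell_neutral_ms = nn,
                       dwell_other_ms = oth,
                       missing_fraction = missing_fraction,
                       excluded = FALSE),
            class = c("dwell_result", "data.frame"))
}

#' Exclude trials with too much missing gaze data
#'
#' A trial is excluded iff strictly more than `threshold` of its
#' stimulus-window samples are invalid ("over 50%": a trial at exactly the
#' threshold is retained).
#'
#' @param results data.frame of [dwell()] rows
#' @param threshold missing-data fraction cutoff
#' @return list: `results` (retained rows), `log` (one row per excluded
#'   trial: participant, trial index, missing fraction), `n_excluded`,
#'   `percent_excluded` (of all recorded trials)
#' @export
exclude_trials <- function(results, threshold = 0.5) {
  results <- as.data.frame(results)
  drop <- results$missing_fraction > threshold
  log <- results[drop, c("participant_id", "trial_index", "missing_fraction")]
  rownames(log) <- NULL
  results$excluded <- drop
  list(results = results[!drop, ],
       log = log,
       n_excluded = sum(drop),
       percent_excluded = 100 * sum(drop) / nrow(results))
}

#' Per-participant disgust-avoidance score
#'
#' The per-trial dwell difference (disgust minus neutral), averaged over
#' retained trials. Negative values indicate avoidance.
#'
#' @param results retained [dwell()] rows for one participant (or several;
#'   grouped by `participant_id`)
#' @return data.frame `participant_id`, `avoidance_score_ms`, `n_trials`;
#'   participants with zero retained trials are absent (missing for this
#'   measure)
#' @export
avoidance_score <- function(results) {
  results <- as.data.frame(results)
  if (nrow(results) == 0)
    return(data.frame(participant_id = character(0),
                      avoidance_score_ms = numeric(0), n_trials = integer(0)))
  diffs <- results$dwell_disgust_ms - results$dwell_neutral_ms
  agg <- aggregate(diffs, by = list(participant_id = results$participant_id),
                   FUN = mean)
  cnt <- aggregate(diffs, by = list(participant_id = results$participant_id),
                   FUN = length)
  data.frame(participant_id = agg$participant_id,
             avoidance_score_ms = agg$x, n_trials = cnt$x)
}

# per-trial binned dwell shares (percent of valid time per bin), from samples
trial_bin_shares <- function(trial, bin_ms) {
  smp <- trial$samples
  lay <- trial$layout
  bin <- floor(smp$t_ms / bin_ms) + 1
  nb <- max(bin)
  vd <- smp$valid
  tab_v <- tabulate(bin[vd], nb)
  tab_d <- tabulate(bin[vd & in_span(smp$x, disgust_span(lay))], nb)
  tab_n <- tabulate(bin[vd & in_span(smp$x, neutral_span(lay))], nb)
  diff <- ifelse(tab_v > 0, 100 * (tab_d - tab_n) / tab_v, NA_real_)
  data.frame(bin = seq_len(nb), diff = diff)
}

#' Within-trial time course of the dwell difference
#'
#' For each time bin from stimulus onset, the share of valid gaze time on
#' each stimulus (percent), differenced disgust minus neutral, averaged
#' first over a participant's trials (stimulus pairs) and then over
#' participants; the standard error is between participants. Computed
#' pooled and, optionally, per presentation number. A participant with zero
#' valid time in a bin contributes missing to that bin.
#'
#' @param trials flat list of `gaze_trial` objects across the cohort
#'   (retained trials only)
#' @param bin_ms bin width (default 500 ms -> 24 bins over the 12 s window)
#' @param by_presentation also return per-presentation curves
#' @return a `time_course` data.frame: `presentation` (`"pooled"` or
#'   `1..3`), `bin_centre_s`, `mean_diff` (percentage points), `sem`, `n`
#' @export
time_course <- function(trials, bin_ms = 500, by_presentation = FALSE) {
  stopifnot(length(trials) > 0)
  per_trial <- lapply(trials, function(tr) {
    b <- trial_bin_shares(tr, bin_ms)
    b$participant_id <- tr$participant_id %||% "p01"
    b$presentation <- tr$presentation %||% 1L
    b
  })
  long <- do.call(rbind, per_trial)
  curve_for <- function(dat, label) {
    pp <- aggregate(diff ~ participant_id + bin, data = dat, FUN = mean,
                    na.action = stats::na.omit)
    mm <- aggregate(diff ~ bin, data = pp, FUN = mean)
    ss <- aggregate(diff ~ bin, data = pp,
                    FUN = function(v) sd(v) / sqrt(length(v)))
    nn <- aggregate(diff ~ bin, data = pp, FUN = length)
    data.frame(presentation = label,
               bin_centre_s = (mm$bin - 0.5) * bin_ms / 1000,
               mean_diff = mm$diff, sem = ss$diff, n = nn$diff)
  }
  out <- curve_for(long, "pooled")
  if (by_presentation)
    for (p in sort(unique(long$presentation)))
      out <- rbind(out, curve_for(long[long$presentation == p, ],
                                  as.character(p)))
  structure(out, class = c("time_course", "data.frame"))
}

#' Run the full preferential-looking computation for a cohort
#'
#' Detect fixations where absent, compute per-trial dwell results, exclude
#' trials with over 50% missing data, and derive per-participant avoidance
#' scores and the pooled time course.
#'
#' @param trials flat list of `gaze_trial` objects
#' @param bin_ms time-course bin width
#' @param missing_threshold trial-exclusion cutoff
#' @param mode dwell mode, see [dwell()]
#' @return list: `dwell` (per-trial table), `exclusions`, `scores`,
#'   `time_course`
#' @export
run_gaze_pipeline <- function(trials, bin_ms = 500, missing_threshold = 0.5,
                              mode = "fixations") {
  res <- do.call(rbind, lapply(trials, dwell, mode = mode))
  exc <- exclude_trials(res, threshold = missing_threshold)
  retained <- trials[vapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    !any(exc$log$participant_id == (tr$participant_id %||% "p01") &
           exc$log$trial_index == tr$trial_index)
  }, logical(1))]
  list(dwell = res, exclusions = exc,
       scores = avoidance_score(exc$results),
       time_course = time_course(retained, bin_ms = bin_ms))
}
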