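#' Area-of-interest layout for a preferential-looking display
#'
#' Two stimuli are shown side by side; each AOI is the horizontal pixel span
#' of one stimulus. Membership uses half-open spans `[x_min, x_max)`,
#' origin top-left, x rightward. Screen geometry is always explicit — there
#' is no standard display.
#'
#' @param left_span,right_span `c(x_min, x_max)` pixel spans
#' @param disgust_side which side carries the disgusting stimulus
#' @param screen_width,screen_height display size in pixels
#' @return an object of class `aoi_layout`
#' @export
aoi_layout <- function(left_span = c(160, 860), right_span = c(1060, 1760),
                       disgust_side = c("left", "right"),
                       screen_width = 1920, screen_height = 1080) {
  disgust_side <- match.arg(disgust_side)
  left_span <- as.numeric(left_span); right_span <- as.numeric(right_span)
  if (length(left_span) != 2 || length(right_span) != 2 ||
      left_span[1] >= left_span[2] || right_span[1] >= right_span[2])
    abort_input("spans must be increasing c(x_min, x_max) pairs")
  if (min(left_span, right_span) < 0 ||
      max(left_span, right_span) > screen_width)
    abort_input("AOI spans must lie within the screen")
  if (max(left_span[1], right_span[1]) < min(left_span[2], right_span[2]))
    abort_input("AOI spans overlap")
  structure(list(left_span = left_span, right_span = right_span,
                 disgust_side = disgust_side,
                 screen_width = screen_width, screen_height = screen_height),
            class = "aoi_layout")
}

disgust_span <- function(layout) {
  if (layout$disgust_side == "left") layout$left_span else layout$right_span
}
neutral_span <- function(layout) {
  if (layout$disgust_side == "left") layout$right_span else layout$left_span
}

#' Trial schedule for the preferential-looking task
#'
#' Every stimulus pair is shown `n_repeats` times; the order of pairs is a
#' seeded shuffle (pairings themselves are fixed).
#'
#' @param n_pairs number of stimulus pairs
#' @param n_repeats presentations per pair
#' @param seed shuffle seed
#' @return data.frame with `trial_index`, `pair_id`, `presentation`
#' @export
trial_schedule <- function(n_pairs = 14, n_repeats = 3, seed = 1) {
  grid <- expand.grid(pair_id = seq_len(n_pairs),
                      presentation = seq_len(n_repeats))
  ord <- with_seed(seed, sample.int(nrow(grid)))
  out <- grid[ord, ]
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("trial_index", "pair_id", "presentation")]
}

#' Configuration for the synthetic gaze generator
#'
#' Emulates the preferential-looking trial structure (1 s fixation cross,
#' 12 s stimulus pair, 3 s inter-trial interval) and the canonical disgust
#' profile: a brief initial approach toward the disgusting stimulus followed
#' by sustained avoidance. Fixation targets are drawn with probability
#' `approach_bias` (toward disgust) before `approach_duration_s` and
#' `avoid_bias` afterwards. Blinks are contiguous runs of invalid samples.
#'
#' @param sampling_rate samples/s (1000 matches a research eye tracker)
#' @param n_pairs,n_repeats trial structure
#' @param fixation_cross_s,stimulus_s,iti_s trial timing, seconds
#' @param approach_duration_s length of the initial approach phase
#' @param approach_bias,avoid_bias probability that a fixation targets the
#'   disgusting stimulus in each phase
#' @param mean_fixation_ms mean fixation duration (~300 ms is typical)
#' @param blink_rate blinks per minute
#' @param blink_duration_ms blink length
#' @param seed RNG seed
#' @return an object of class `gaze_sim_config`
#' @export
gaze_sim_config <- function(sampling_rate = 1000, n_pairs = 14, n_repeats = 3,
                            fixation_cross_s = 1, stimulus_s = 12, iti_s = 3,
                            approach_duration_s = 1,
                            approach_bias = 0.7, avoid_bias = 0.3,
                            mean_fixation_ms = 300,
                            blink_rate = 12, blink_duration_ms = 250,
                            seed = 1) {
  if (approach_bias < 0 || approach_bias > 1 ||
      avoid_bias < 0 || avoid_bias > 1)
    abort_input("biases must lie in [0, 1]")
  if (sampling_rate <= 0 || stimulus_s <= 0)
    abort_input("sampling_rate and stimulus_s must be > 0")
  structure(list(sampling_rate = sampling_rate, n_pairs = n_pairs,
                 n_repeats = n_repeats, fixation_cross_s = fixation_cross_s,
                 stimulus_s = stimulus_s, iti_s = iti_s,
                 approach_duration_s = approach_duration_s,
                 approach_bias = approach_bias, avoid_bias = avoid_bias,
                 mean_fixation_ms = mean_fixation_ms,
                 blink_rate = blink_rate,
                 blink_duration_ms = blink_duration_ms, seed = seed),
            class = "gaze_sim_config")
}

# one trial's ground-truth fixation/saccade segment table
simulate_fixation_events <- function(cfg, layout) {
  win <- cfg$stimulus_s * 1000
  sacc <- 30
  segs <- list()
  t_cur <- 0
  # initial center fixation left over from the fixation cross
  dur0 <- runif(1, 150, 250)
  cx <- mean(c(layout$left_span[2], layout$right_span[1]))
  segs[[1]] <- data.frame(start_ms = 0, end_ms = dur0, x = cx,
                          y = layout$screen_height / 2, target = "other")
  t_cur <- dur0
  while (t_cur < win) {
    t_cur <- t_cur + sacc
    if (t_cur >= win) break
    bias <- if (t_cur < cfg$approach_duration_s * 1000) cfg$approach_bias
            else cfg$avoid_bias
    tgt <- if (runif(1) < bias) "disgust" else "neutral"
    span <- if (tgt == "disgust") disgust_span(layout) else neutral_span(layout)
    inset <- 0.1 * diff(span)
    dur <- max(50, rgamma(1, shape = 4, scale = cfg$mean_fixation_ms / 4))
    # a fixation never runs across the approach/avoid phase boundary: the
    # phase switch forces a refixation, so degenerate biases are exact
    appr_end <- cfg$approach_duration_s * 1000
    if (t_cur < appr_end && t_cur + dur > appr_end) dur <- appr_end - t_cur
    segs[[length(segs) + 1]] <- data.frame(
      start_ms = t_cur, end_ms = min(win, t_cur + dur),
      x = runif(1, span[1] + inset, span[2] - inset),
      y = layout$screen_height / 2 + rnorm(1, 0, 30), target = tgt)
    t_cur <- t_cur + dur
  }
  do.call(rbind, segs)
}

#' Generate synthetic preferential-looking trials with ground truth
#'
#' The disgusting stimulus side alternates over trials (counterbalanced,
#' then shuffled with the trial order). Sample streams cover the 12 s
#' stimulus window; ground-truth fixations are attached to every trial.
#'
#' @param cfg a [gaze_sim_config()]
#' @param layout an [aoi_layout()] (its `disgust_side` is overridden per
#'   trial)
#' @param participant_id identifier
#' @return list of `gaze_trial` objects (fields `trial_index`, `pair_id`,
#'   `presentation`, `samples`, `fixations`, `layout`)
#' @export
generate_gaze <- function(cfg, layout = aoi_layout(),
                          participant_id = "sim01") {
  stopifnot(inherits(cfg, "gaze_sim_config"), inherits(layout, "aoi_layout"))
  with_seed(cfg$seed, {
    sched <- local({
      grid <- expand.grid(pair_id = seq_len(cfg$n_pairs),
                          presentation = seq_len(cfg$n_repeats))
      grid[sample.int(nrow(grid)), ]
    })
    sides <- sample(rep_len(c("left", "right"), nrow(sched)))
    n_samp <- round(cfg$stimulus_s * cfg$sampling_rate)
    step <- 1000 / cfg$sampling_rate
    t_ms <- (seq_len(n_samp) - 1) * step
    lapply(seq_len(nrow(sched)), function(i) {
      lay <- layout
      lay$disgust_side <- sides[i]
      segs <- simulate_fixation_events(cfg, lay)
      # piecewise-constant position over fixations, linear over saccades
      xi <- approx(x = c(rbind(segs$start_ms, segs$end_ms)),
                   y = rep(segs$x, each = 2), xout = t_ms, rule = 2)$y
      yi <- approx(x = c(rbind(segs$start_ms, segs$end_ms)),
                   y = rep(segs$y, each = 2), xout = t_ms, rule = 2)$y
      xi <- xi + rnorm(n_samp, 0, 1)
      yi <- yi + rnorm(n_samp, 0, 1)
      valid <- rep(TRUE, n_samp)
      if (cfg$blink_rate > 0) {
        n_bl <- rpois(1, cfg$blink_rate * cfg$stimulus_s / 60)
        if (n_bl > 0) {
          starts <- runif(n_bl, 0, cfg$stimulus_s * 1000)
          for (b in starts) {
            idx <- which(t_ms >= b & t_ms < b + cfg$blink_duration_ms)
            valid[idx] <- FALSE
          }
        }
      }
      xi[!valid] <- NA_real_; yi[!valid] <- NA_real_
      fix <- segs[segs$target != "other" | segs$start_ms == 0, ]
      structure(list(trial_index = i,
                     pair_id = sched$pair_id[i],
                     presentation = sched$presentation[i],
                     participant_id = participant_id,
                     samples = data.frame(t_ms = t_ms, x = xi, y = yi,
                                          valid = valid),
                     fixations = data.frame(start_ms = fix$start_ms,
                                            end_ms = fix$end_ms,
                                            x = fix$x, y = fix$y),
                     layout = lay),
                class = "gaze_trial")
    })
  })
}

#' @export
print.gaze_trial <- function(x, ...) {
  cat(sprintf(
    "<gaze_trial> %d (pair %d, presentation %d): %d samples, %d fixations, disgust on the %s\n",
    x$trial_index, x$pair_id, x$presentation, nrow(x$samples),
    nrow(x$fixations), x$layout$disgust_side))
  invisible(x)
}
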