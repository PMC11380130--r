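lay_left <- aoi_layout(disgust_side = "left")

test_that("detect_fixations finds still periods and splits on saccades", {
  t_ms <- 0:999
  still <- data.frame(t_ms = t_ms, x = 500, y = 540, valid = TRUE)
  fx <- detect_fixations(still[1:500, ])
  expect_equal(nrow(fx), 1)
  expect_equal(fx$end_ms - fx$start_ms, 499, tolerance = 2)
  # two still periods with a fast jump
  x <- c(rep(300, 400), seq(300, 1400, length.out = 30), rep(1400, 570))
  two <- data.frame(t_ms = t_ms, x = x, y = 540, valid = TRUE)
  expect_equal(nrow(detect_fixations(two)), 2)
  # empty stream
  expect_equal(nrow(detect_fixations(still[0, ])), 0)
  expect_error(detect_fixations(data.frame(t_ms = c(1, 1, 2), x = 0, y = 0,
                                           valid = TRUE)), "increasing")
})

test_that("detected fixations match the generator's ground truth", {
  # pooled over trials; >90% of blink-free ground-truth fixations are
  # matched by a detected fixation's midpoint falling inside them
  trials <- generate_gaze(gaze_sim_config(seed = 5))
  matched <- 0; total <- 0
  for (tr in trials[1:12]) {
    fx <- detect_fixations(tr$samples)
    gt <- tr$fixations
    smp <- tr$samples
    blinked <- vapply(seq_len(nrow(gt)), function(i)
      any(!smp$valid[smp$t_ms >= gt$start_ms[i] & smp$t_ms <= gt$end_ms[i]]),
      logical(1))
    gt <- gt[!blinked & (gt$end_ms - gt$start_ms) >= 80, ]
    mid <- (fx$start_ms + fx$end_ms) / 2
    matched <- matched + sum(vapply(seq_len(nrow(gt)), function(i)
      any(mid >= gt$start_ms[i] & mid <= gt$end_ms[i]), logical(1)))
    total <- total + nrow(gt)
  }
  expect_gt(matched / total, 0.9)
})

test_that("dwell sums fixation durations into the correct AOI", {
  # forced sums: 1000 ms on disgust (left), 3000 ms on neutral (right)
  fx <- data.frame(start_ms = c(0, 2000), end_ms = c(1000, 5000),
                   x = c(500, 1400), y = 540)
  d <- dwell(make_trial(fx, lay_left))
  expect_equal(d$dwell_disgust_ms, 1000)
  expect_equal(d$dwell_neutral_ms, 3000)
  expect_equal(d$missing_fraction, 0)
  # all fixations in the neutral span
  fx2 <- data.frame(start_ms = c(0, 4000), end_ms = c(3000, 9000),
                    x = c(1100, 1700), y = 540)
  d2 <- dwell(make_trial(fx2, lay_left))
  expect_equal(d2$dwell_neutral_ms, 8000)
  expect_equal(d2$dwell_disgust_ms, 0)
  # centroid in the gap between spans counts as other
  fx3 <- data.frame(start_ms = 0, end_ms = 2000, x = 950, y = 540)
  d3 <- dwell(make_trial(fx3, lay_left))
  expect_equal(d3$dwell_other_ms, 2000)
  expect_equal(d3$dwell_disgust_ms + d3$dwell_neutral_ms, 0)
  # half-open span: a centroid exactly on x_max falls outside
  on_edge <- data.frame(start_ms = 0, end_ms = 1000,
                        x = lay_left$left_span[2], y = 540)
  expect_equal(dwell(make_trial(on_edge, lay_left))$dwell_disgust_ms, 0)
  expect_error(dwell(structure(list(samples = data.frame()),
                               class = "gaze_trial")), "layout")
})

test_that("dwell conservation holds for generated trials in both modes", {
  trials <- generate_gaze(gaze_sim_config(sampling_rate = 200, seed = 12))
  for (tr in trials[1:8]) {
    for (mode in c("fixations", "samples")) {
      d <- dwell(tr, mode = mode)
      tot <- d$dwell_disgust_ms + d$dwell_neutral_ms + d$dwell_other_ms
      expect_lte(tot, 12000 + 1e-9)
      expect_gte(tot, 0)
    }
  }
})

test_that("trial exclusion uses a strict 'over 50%' rule and logs", {
  res <- do.call(rbind, list(
    dwell(make_trial(data.frame(start_ms = 0, end_ms = 1000, x = 500,
                                y = 540), lay_left,
                     invalid_fraction = 0.51, trial_index = 1)),
    dwell(make_trial(data.frame(start_ms = 0, end_ms = 1000, x = 500,
                                y = 540), lay_left,
                     invalid_fraction = 0.50, trial_index = 2)),
    dwell(make_trial(data.frame(start_ms = 0, end_ms = 1000, x = 500,
                                y = 540), lay_left,
                     invalid_fraction = 0, trial_index = 3))))
  exc <- exclude_trials(res)
  expect_equal(exc$n_excluded, 1)
  expect_equal(exc$log$trial_index, 1)
  expect_equal(sort(exc$results$trial_index), c(2, 3))
  # exclusion monotonicity: a higher threshold never excludes more
  set.seed(3)
  mf <- runif(200)
  res2 <- data.frame(participant_id = "p", trial_index = 1:200,
                     dwell_disgust_ms = 0, dwell_neutral_ms = 0,
                     dwell_other_ms = 0, missing_fraction = mf,
                     excluded = FALSE)
  counts <- vapply(c(0.2, 0.4, 0.5, 0.7, 0.9),
                   function(th) exclude_trials(res2, th)$n_excluded, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("avoidance_score averages per-trial dwell differences", {
  fx <- function(dd, dn, idx) {
    f <- data.frame(start_ms = c(0, 6000), end_ms = c(dd, 6000 + dn),
                    x = c(500, 1400), y = 540)
    dwell(make_trial(f, lay_left, trial_index = idx))
  }
  res <- rbind(fx(2000, 6000, 1), fx(1000, 5000, 2))
  sc <- avoidance_score(res)
  expect_equal(sc$avoidance_score_ms, -4000)
  # equal dwells -> zero
  res0 <- rbind(fx(3000, 3000, 1), fx(1000, 1000, 2))
  expect_equal(avoidance_score(res0)$avoidance_score_ms, 0)
  # zero retained trials -> participant missing
  expect_equal(nrow(avoidance_score(res[0, ])), 0)
})

test_that("avoidance sign follows the generator's bias at cohort scale", {
  scores <- vapply(1:5, function(rep) {
    trials <- unlist(lapply(1:4, function(p) {
      generate_gaze(gaze_sim_config(sampling_rate = 100, n_pairs = 7,
                                    n_repeats = 2, avoid_bias = 0.3,
                                    seed = rep * 100 + p),
                    participant_id = sprintf("p%02d", p))
    }), recursive = FALSE)
    mean(run_gaze_pipeline(trials)$scores$avoidance_score_ms)
  }, numeric(1))
  expect_true(all(scores < 0))
})

test_that("time_course bins, normalisation and degenerate cases", {
  # all gaze on neutral always -> every bin at -100% with zero SEM
  fxn <- data.frame(start_ms = 0, end_ms = 12000, x = 1400, y = 540)
  trials <- lapply(1:3, function(p)
    make_trial(fxn, lay_left, participant_id = sprintf("p%d", p)))
  tc <- time_course(trials, bin_ms = 500)
  expect_equal(nrow(tc), 24)                 # 12 s / 500 ms
  expect_true(all(abs(tc$mean_diff + 100) < 1e-9))
  expect_true(all(tc$sem == 0))
  expect_true(all(tc$mean_diff >= -100 & tc$mean_diff <= 100))
  # per-presentation split returns extra curves
  tc2 <- time_course(trials, bin_ms = 1000, by_presentation = TRUE)
  expect_true("pooled" %in% tc2$presentation)
  expect_equal(sum(tc2$presentation == "pooled"), 12)
})

test_that("time course shows approach then avoidance for biased cohorts", {
  trials <- unlist(lapply(1:6, function(p)
    generate_gaze(gaze_sim_config(sampling_rate = 100, approach_bias = 0.7,
                                  avoid_bias = 0.3, seed = 40 + p),
                  participant_id = sprintf("p%02d", p))),
    recursive = FALSE)
  tc <- run_gaze_pipeline(trials)$time_course
  expect_gt(mean(tc$mean_diff[tc$bin_centre_s < 1]), 0)
  expect_true(all(tc$mean_diff[tc$bin_centre_s > 2] < 0))
})
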