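test_that("noiseless EGG channels are exact mixtures of the sinusoid sources", {
  cfg <- quick_egg_config(noise_sd = 0, spike_rate = 0, drift_slope = 0,
                          attenuation_delta = 0, seed = 2)
  sim <- generate_egg(cfg)
  expect_equal(unname(sim$recording$channels),
               unname(sim$ground_truth$sources %*% t(cfg$mixing_matrix)),
               tolerance = 1e-12)
  # spectrum peak at 3 cpm (dominant source), independent periodogram
  orc <- oracle_periodogram(sim$recording$channels[1:(300 * 200), 1], 200)
  expect_equal(orc$freq_cpm[which.max(orc$power)], 3, tolerance = 0.05)
})

test_that("normogastric attenuation follows the (1 - delta)^2 power law", {
  for (delta in c(0.2, 0.5)) {
    cfg <- quick_egg_config(noise_sd = 0, spike_rate = 0, drift_slope = 0,
                            attenuation_delta = delta, seed = 4)
    sim <- generate_egg(cfg)
    fs <- cfg$sampling_rate
    ch <- sim$recording$channels[, 2]
    dis <- oracle_periodogram(ch[1:(300 * fs)], fs)
    neu <- oracle_periodogram(ch[(300 * fs + 1):(600 * fs)], fs)
    nrm <- dis$freq_cpm >= 2 & dis$freq_cpm <= 4
    ratio <- max(dis$power[nrm]) / max(neu$power[nrm])
    expect_equal(ratio, (1 - delta)^2, tolerance = 0.01)
  }
})

test_that("EGG generation is seed-deterministic and validates its config", {
  cfg <- quick_egg_config(seed = 6)
  s1 <- generate_egg(cfg); s2 <- generate_egg(cfg)
  expect_identical(s1$recording$channels, s2$recording$channels)
  expect_identical(s1$ground_truth$sources, s2$ground_truth$sources)
  expect_error(egg_sim_config(attenuation_delta = 1), "attenuation_delta")
  expect_error(egg_sim_config(block_duration = 0), "block_duration")
  bad_mix <- matrix(c(1, 0.5, 1.5, 2, 1, 3, 3, 1.5, 4.5, 1, 0.5, 1.5),
                    4, 3, byrow = TRUE)  # rank 2
  expect_error(egg_sim_config(mixing_matrix = bad_mix), "rank deficient")
})

test_that("block order controls which block comes first", {
  cfg <- quick_egg_config(block_order = "neutral_first", seed = 1)
  ev <- generate_egg(cfg)$recording$events
  expect_equal(ev$label[which.min(ev$start_s)], "block_neutral")
})

test_that("gaze trials honour timing, counts and degenerate biases", {
  cfg <- gaze_sim_config(sampling_rate = 250, seed = 8, blink_rate = 0,
                         avoid_bias = 0)
  trials <- generate_gaze(cfg)
  expect_length(trials, 14 * 3)
  # timing conservation: valid + invalid == stimulus_s * sampling_rate
  expect_true(all(vapply(trials, function(tr) nrow(tr$samples), 1L) ==
                    12 * 250))
  # blink_rate = 0 -> no missing data
  expect_true(all(vapply(trials, function(tr) mean(!tr$samples$valid), 1) == 0))
  # avoid_bias = 0: after the approach phase (plus one saccade) every
  # sample sits in the neutral AOI
  for (tr in trials[1:10]) {
    nsp <- gastrogaze:::neutral_span(tr$layout)
    post <- tr$samples[tr$samples$t_ms >= 1000 + 40, ]
    expect_true(all(post$x >= nsp[1] - 3 & post$x < nsp[2] + 3))
  }
})

test_that("gaze generation is seed-deterministic; schedule covers pair x repeat", {
  cfg <- gaze_sim_config(sampling_rate = 100, seed = 3)
  t1 <- generate_gaze(cfg); t2 <- generate_gaze(cfg)
  expect_identical(t1[[5]]$samples, t2[[5]]$samples)
  combos <- table(vapply(t1, `[[`, 1L, "pair_id"),
                  vapply(t1, `[[`, 1L, "presentation"))
  expect_true(all(combos == 1))
  expect_error(aoi_layout(left_span = c(100, 1000),
                          right_span = c(900, 1800)), "overlap")
})

test_that("cohort generator recovers the latent questionnaire correlation", {
  sim <- generate_cohort(cohort_sim_config(n_participants = 500,
                                           latent_correlation = 0.5,
                                           seed = 21))
  r <- cor(sim$cohort$dsr_total, sim$cohort$tdds_total)
  expect_equal(r, 0.5, tolerance = 0.1)
  sim0 <- generate_cohort(cohort_sim_config(n_participants = 500,
                                            latent_correlation = 0,
                                            seed = 22))
  expect_lt(abs(cor(sim0$cohort$child_22_total, sim0$cohort$tdds_total)),
            0.15)
})

test_that("cohort family structure and validation behave", {
  sim <- generate_cohort(cohort_sim_config(n_participants = 40,
                                           sibling_fraction = 0, seed = 2))
  expect_equal(anyDuplicated(sim$cohort$parent_id), 0)
  sim2 <- generate_cohort(cohort_sim_config(n_participants = 40,
                                            sibling_fraction = 0.3, seed = 2))
  expect_gt(sum(duplicated(sim2$cohort$parent_id)), 0)
  expect_true(all(sim2$cohort$age_months >= 60 &
                    sim2$cohort$age_months <= 167))
  expect_error(cohort_sim_config(n_participants = 1, sibling_fraction = 0.5),
               "at least 2")
  expect_error(cohort_sim_config(latent_correlation = 1.2), "latent_correlation")
  # determinism
  a <- generate_cohort(cohort_sim_config(n_participants = 20, seed = 9))
  b <- generate_cohort(cohort_sim_config(n_participants = 20, seed = 9))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$responses, b$responses)
})
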