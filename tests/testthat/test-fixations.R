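geom <- screen_geometry()

test_that("constant valid gaze produces exactly one full-trial fixation", {
  gz <- make_gaze(data.frame(from_ms = 0, to_ms = 2500, x = 700, y = 400,
                             valid = 1))
  fx <- detect_fixations(gz, geom)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$onset_ms, 0)
  expect_equal(fx$duration_ms, 2500)
  expect_equal(fx$x, 700)
  expect_equal(fx$source, "binocular")
})

test_that("short invalid gaps are interpolated, long ones are not", {
  # 60-ms blink inside a stable fixation: interpolated, one fixation
  gz <- make_gaze(data.frame(from_ms = c(0, 1000, 1060),
                             to_ms = c(1000, 1060, 2500),
                             x = c(700, 0, 700), y = c(400, 0, 400),
                             valid = c(1, 0, 1)))
  fx <- detect_fixations(gz, geom)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 2500)
  # 150-ms gap: beyond the 75-ms limit, two separate fixations remain
  # (the merge rule also cannot bridge it: 150 > 75)
  gz2 <- make_gaze(data.frame(from_ms = c(0, 1000, 1150),
                              to_ms = c(1000, 1150, 2500),
                              x = c(700, 0, 700), y = c(400, 0, 400),
                              valid = c(1, 0, 1)))
  fx2 <- detect_fixations(gz2, geom)
  expect_equal(nrow(fx2), 2)
  expect_lt(fx2$offset_ms[1], 1010)
  expect_gte(fx2$onset_ms[2], 1150)
})

test_that("adjacent same-place fixations split by a saccadic excursion merge", {
  # 60 ms of fast motion between two stable segments at the same spot:
  # the excursion samples exceed the velocity threshold, leaving two
  # fixations 60 ms and < 0.5 degrees apart -> merged
  n_exc <- 7  # ~58 ms of samples sweeping far away and back
  sweep_x <- 700 + c(200, 400, 600, 700, 600, 400, 200)
  seg <- data.frame(
    from_ms = c(0, 1000 + (0:(n_exc - 1)) * 8.33, 1058),
    to_ms = c(1000, 1000 + (1:n_exc) * 8.33, 2500),
    x = c(700, sweep_x, 700), y = 400, valid = 1
  )
  fx <- detect_fixations(make_gaze(seg), geom)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 2500)
})

test_that("fixations shorter than 100 ms are excluded", {
  gz <- make_gaze(data.frame(from_ms = c(0, 90), to_ms = c(90, 2500),
                             x = c(700, 0), y = c(400, 0),
                             valid = c(1, 0)))
  fx <- detect_fixations(gz, geom)
  expect_equal(nrow(fx), 0)
  # at 110 ms the segment survives
  gz2 <- make_gaze(data.frame(from_ms = c(0, 110), to_ms = c(110, 2500),
                              x = c(700, 0), y = c(400, 0),
                              valid = c(1, 0)))
  expect_equal(nrow(detect_fixations(gz2, geom)), 1)
})

test_that("monocular data are used when one eye is missing", {
  gz <- make_gaze(data.frame(from_ms = 0, to_ms = 2500, x = 700, y = 400,
                             valid = 1))
  gz$rx <- NA_real_; gz$ry <- NA_real_; gz$r_valid <- 0L
  fx <- detect_fixations(gz, geom)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$source, "left_only")
})

test_that("merging is idempotent and conjunctive in both criteria", {
  fx <- tibble::tibble(
    onset_ms = c(0, 250, 500, 900),
    offset_ms = c(200, 450, 820, 2000),
    x = c(700, 703, 760, 700), y = rep(400, 4),
    n_samples = c(24, 24, 38, 132), source = "binocular"
  )
  # gap 0-1: 50 ms, angle ~0.07 deg -> merge; gap 1-2: 50 ms but 57 px
  # (~1.4 deg) -> no; gap 2-3: 80 ms -> no
  m1 <- merge_fixations(fx, geom)
  expect_equal(nrow(m1), 3)
  expect_equal(m1$offset_ms[1], 450)
  m2 <- merge_fixations(m1, geom)
  expect_identical(m1, m2)
})

test_that("lowering the minimum duration never reduces the fixation count", {
  spec <- small_spec(seed = 3)
  pp <- make_participant_params(spec, "autistic")
  d <- build_stimulus_set(default_lexicon())
  for (seed in 1:5) {
    gz <- simulate_trial_gaze(d[1, ], pp, seed = seed)$gaze
    n_strict <- nrow(detect_fixations(gz, geom, ivt_params(min_duration_ms = 100)))
    n_loose <- nrow(detect_fixations(gz, geom, ivt_params(min_duration_ms = 60)))
    expect_gte(n_loose, n_strict)
  }
})

test_that("zero-noise synthetic trials are recovered exactly as the latent occupancy", {
  spec <- small_spec(jitter_sd_px = 0, eye_noise_px = 0, blink_rate_hz = 0)
  pp <- make_participant_params(spec, "nt")
  d <- build_stimulus_set(default_lexicon())
  lay <- aoi_layout()
  for (seed in 1:8) {
    sim <- simulate_trial_gaze(d[3, ], pp, seed = seed)
    occ <- bin_fixations(assign_aoi(detect_fixations(sim$gaze, geom), d[3, ], lay))
    conds <- c("target", "agent_related", "action_related", "unrelated")
    for (k in 1:4) {
      expect_identical(occ[[conds[k]]], as.integer(sim$states == k))
    }
  }
})

test_that("total fixation time never exceeds the trial window", {
  spec <- small_spec(seed = 6)
  pp <- make_participant_params(spec, "nt")
  d <- build_stimulus_set(default_lexicon())
  for (seed in 1:5) {
    gz <- simulate_trial_gaze(d[2, ], pp, seed = seed)$gaze
    fx <- detect_fixations(gz, geom)
    expect_lte(sum(fx$duration_ms), 2500)
    if (nrow(fx) > 1) {
      expect_true(all(fx$onset_ms[-1] >= fx$offset_ms[-nrow(fx)]))
    }
  }
})
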