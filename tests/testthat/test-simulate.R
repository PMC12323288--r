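test_that("a 2500-ms trial at 120 Hz yields 300 samples with integer timestamps", {
  spec <- small_spec()
  pp <- make_participant_params(spec, "nt")
  d <- build_stimulus_set(default_lexicon())
  sim <- simulate_trial_gaze(d[1, ], pp, seed = 3)
  expect_equal(nrow(sim$gaze), 300)
  expect_true(all(sim$gaze$t_ms == round(sim$gaze$t_ms)))
  expect_true(all(diff(sim$gaze$t_ms) > 0))
  expect_length(sim$states, 50)
})

test_that("a degenerate process fixed on one AOI yields a single full-trial fixation there", {
  spec <- small_spec(jitter_sd_px = 0, eye_noise_px = 0, blink_rate_hz = 0)
  pp <- make_participant_params(spec, "nt")
  # saturate the agent ramp from the start and park all redraw mass on the
  # target so the latent process is pinned to one AOI for the whole trial
  pp$agent_mid_ms <- -5000
  pp$baseline <- c(target = 1 - 1e-9, agent_related = 1e-10,
                   action_related = 1e-10, unrelated = 1e-10)
  pp$bias <- 1 - 1e-9
  pp$action_bump <- 0
  pp$agent_end <- 1e-10
  d <- build_stimulus_set(default_lexicon())
  sim <- simulate_trial_gaze(d[1, ], pp, seed = 5)
  expect_true(all(sim$states == 1))
  fx <- detect_fixations(sim$gaze)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 2500)
  fx <- assign_aoi(fx, d[1, ], aoi_layout())
  expect_equal(fx$condition, "target")
})

test_that("Monte-Carlo occupancy matches the forward-recursion marginal within 3 SEs", {
  spec <- small_spec()
  pp <- make_participant_params(spec, "nt")
  M <- latent_marginal(pp)
  n_rep <- 3000
  acc <- matrix(0, 50, 5)
  withr::with_seed(11, {
    for (r in seq_len(n_rep)) {
      s <- simulate_latent_states(pp)
      for (k in 1:5) acc[, k] <- acc[, k] + (s == k)
    }
  })
  emp <- acc / n_rep
  se <- sqrt(pmax(M * (1 - M), 1e-6) / n_rep)
  expect_lt(max(abs(emp - M) / se), 3)
})

test_that("the marginal target occupancy crosses its halfway level near the ramp midpoint", {
  # the 50% point of the target rise (midway between pre-verb and
  # asymptotic levels) should sit within ~1 dwell of the generating
  # midpoint verb_onset + latency (dwell persistence adds lag)
  spec <- small_spec()
  pp <- make_participant_params(spec, "nt", latency = 150)
  M <- latent_marginal(pp)
  tgt <- M[, "target"]
  centers <- (0:49) * 50 + 25
  halfway <- (min(tgt[centers < 750]) + max(tgt)) / 2
  cross <- centers[which(tgt >= halfway)[1]]
  expect_lt(abs(cross - (750 + 150)), 300)
})

test_that("cohort simulation is fully reproducible and shaped as specified", {
  spec <- small_spec(n1 = 3, n2 = 4, seed = 9)
  c1 <- simulate_cohort(spec, level = "tensor")
  c2 <- simulate_cohort(spec, level = "tensor")
  expect_identical(c1$tensor, c2$tensor)
  expect_identical(c1$scores, c2$scores)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_equal(nrow(c1$scores), 7)
  expect_equal(nrow(c1$tensor), 7 * 24 * 50)
  expect_equal(sum(is.na(c1$scores$cars_total)), 4)  # CARS first group only
  expect_true(all(!is.na(c1$scores$aq_total)))
  # subscales sum to the total
  subs <- c1$scores[, c("aq_social_skills", "aq_attention_switching",
                        "aq_attention_to_detail", "aq_communication",
                        "aq_imagination")]
  expect_equal(rowSums(subs), c1$scores$aq_total)
  expect_error(cohort_spec(n_per_group = c(a = 1, b = 5)), "at least 2")
})

test_that("a null score link leaves AQ uncorrelated with realized latency", {
  sl <- test_score_link(c("autistic", "nt"))
  sl$aq_latency <- 0; sl$aq_bias <- 0
  rs <- vapply(1:5, function(seed) {
    spec <- cohort_spec(score_link = sl, seed = seed)
    coh <- simulate_cohort(spec, level = "tensor")
    j <- dplyr::inner_join(coh$scores, coh$ground_truth$participants,
                           by = c("participant_id", "group"))
    ja <- j[j$group == "autistic", ]
    stats::cor(ja$aq_total, ja$latency_ms)
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("per-participant gaze tables carry blink gaps and valid coordinates", {
  spec <- small_spec(n1 = 2, n2 = 2, blink_rate_hz = 1.5, seed = 4)
  coh <- simulate_cohort(spec, level = "gaze")
  gz <- coh$gaze
  expect_equal(nrow(gz), 4 * 24 * 300)
  expect_true(any(gz$l_valid == 0))
  expect_true(all(is.na(gz$lx[gz$l_valid == 0])))
  ok <- gz$l_valid == 1
  expect_true(all(gz$lx[ok] >= 0 & gz$lx[ok] <= 1920))
  expect_true(all(gz$ly[ok] >= 0 & gz$ly[ok] <= 1080))
})
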