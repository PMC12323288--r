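#' Specification of a synthetic two-group cohort
#'
#' Collects every parameter of the synthetic gaze generator: cohort shape,
#' the per-group latent fixation process, measurement noise, and the linear
#' links tying each participant's realized process parameters to simulated
#' questionnaire scores. Defaults describe a study with 45 autistic and 52
#' neurotypical (NT) children, 24 trials each, 120-Hz binocular tracking of
#' a 1920x1080 screen, and sentence landmarks at 750/1300/2100 ms.
#'
#' @details
#' The latent process is a dwell-based categorical process over five states
#' (the four AOI conditions plus an off-AOI background state) on the 50-ms
#' bin grid. At each dwell boundary the next state is drawn from
#' time-varying redraw probabilities composed of two logistic phases: an
#' agent-based ramp (midpoint `agent_mid_ms`) carries all four conditions
#' from a common `start_prob` to their pre-verb `baseline` levels (target
#' and agent-related elevated), then a verb-based ramp with midpoint
#' `verb onset + onset_latency_ms` and scale `ramp_scale_ms` carries the
#' target up to `target_bias` and the agent-related condition down to
#' `agent_end`; the action-related probability additionally carries a
#' transient Gaussian bump after verb onset (the verb-compatible candidate
#' of the TRACE-like incremental strategy); the background state absorbs
#' the remainder.
#' Dwells last a minimum of `min_dwell_bins` bins plus a geometric tail, so
#' every latent dwell is at least 150 ms by default and survives the 100-ms
#' minimum-duration fixation filter. The exact per-bin marginal occupancy
#' implied by this process is available from [latent_marginal()].
#'
#' @param n_per_group Named counts, e.g. `c(autistic = 45, nt = 52)`. Both
#'   must be at least 2.
#' @param n_trials Trials per participant (a multiple of 4 uses the full
#'   counterbalanced design).
#' @param groups Named list of per-group parameter lists; see
#'   [group_params()].
#' @param latency_sd_ms,bias_sd Between-participant SDs of the gaze-shift
#'   latency (ms) and asymptotic target redraw probability.
#' @param latency_range,bias_range Truncation bounds for participant draws.
#' @param min_dwell_bins,mean_dwell_bins Minimum and mean dwell length of
#'   the latent process, in 50-ms bins.
#' @param jitter_sd_px Stationary SD of the AR(1) gaze-position jitter.
#' @param jitter_ar AR(1) coefficient of the jitter (drift-like noise; high
#'   values keep sample-to-sample velocity below saccade thresholds).
#' @param eye_noise_px Per-eye independent noise SD added to each eye's
#'   sample.
#' @param blink_rate_hz Expected blinks per second.
#' @param blink_dur_range_ms Blink duration range (uniform); the default
#'   50-300 ms straddles the 75-ms gap-interpolation limit so both
#'   interpolated and non-interpolated gaps occur.
#' @param score_link Coefficients of the linear score links; see Details of
#'   [simulate_cohort()].
#' @param accuracy_logit Named per-group conditional logit of trial
#'   accuracy; the defaults give marginal accuracies of about 93.4% and
#'   95.9% under the default participant random-intercept SD.
#' @param accuracy_re_sd SD of the participant random intercept on the
#'   accuracy logit scale (heterogeneity large enough that a ~2-point
#'   group accuracy gap is usually not significant at this sample size).
#' @param bin_width_ms,window_ms Analysis binning (50-ms bins over
#'   0-2500 ms).
#' @param geometry A [screen_geometry()].
#' @param layout An [aoi_layout()].
#' @param seed Integer master seed for the cohort.
#' @return A validated `vwp_cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = c(autistic = 45, nt = 52),
                        n_trials = 24,
                        groups = list(
                          autistic = group_params(onset_latency_ms = 830,
                                                  target_bias = 0.45),
                          nt = group_params(onset_latency_ms = 700,
                                            target_bias = 0.55)
                        ),
                        latency_sd_ms = 200, bias_sd = 0.05,
                        latency_range = c(100, 1350),
                        bias_range = c(0.20, 0.66),
                        min_dwell_bins = 3, mean_dwell_bins = 6,
                        jitter_sd_px = 15, jitter_ar = 0.95,
                        eye_noise_px = 2,
                        blink_rate_hz = 0.2,
                        blink_dur_range_ms = c(50, 300),
                        score_link = default_score_link(),
                        accuracy_logit = c(autistic = 4.268, nt = 4.953),
                        accuracy_re_sd = 2.2,
                        bin_width_ms = 50, window_ms = c(0, 2500),
                        geometry = screen_geometry(),
                        layout = aoi_layout(geometry = geometry),
                        seed = 1L) {
  if (length(n_per_group) != 2 || is.null(names(n_per_group))) {
    stop("n_per_group must be a named length-2 vector")
  }
  if (any(n_per_group < 2)) {
    stop("n_per_group must be at least 2 per group (statistics undefined)")
  }
  if (!setequal(names(groups), names(n_per_group))) {
    stop("groups must be named like n_per_group")
  }
  stopifnot(min_dwell_bins >= 1, mean_dwell_bins >= min_dwell_bins,
            jitter_sd_px >= 0, blink_rate_hz >= 0,
            diff(window_ms) %% bin_width_ms == 0)
  spec <- structure(
    list(n_per_group = n_per_group, n_trials = n_trials, groups = groups,
         latency_sd_ms = latency_sd_ms, bias_sd = bias_sd,
         latency_range = latency_range, bias_range = bias_range,
         min_dwell_bins = min_dwell_bins, mean_dwell_bins = mean_dwell_bins,
         jitter_sd_px = jitter_sd_px, jitter_ar = jitter_ar,
         eye_noise_px = eye_noise_px,
         blink_rate_hz = blink_rate_hz,
         blink_dur_range_ms = blink_dur_range_ms,
         score_link = score_link,
         accuracy_logit = accuracy_logit, accuracy_re_sd = accuracy_re_sd,
         bin_width_ms = bin_width_ms, window_ms = window_ms,
         geometry = geometry, layout = layout, seed = as.integer(seed)),
    class = "vwp_cohort_spec"
  )
  # Probabilities must stay a sub-distribution at the extremes of the
  # participant parameter ranges.
  for (g in names(groups)) {
    pp <- make_participant_params(spec, g,
                                  latency = latency_range[1],
                                  bias = bias_range[2])
    pr <- redraw_probs(pp, seq(0, window_ms[2], by = 10))
    if (any(rowSums(pr[, 1:4]) > 1 + 1e-12)) {
      stop("invalid cohort spec: AOI probabilities exceed 1 for group ", g,
           " at the upper bias bound")
    }
    if (any(pr < -1e-12)) {
      stop("invalid cohort spec: negative AOI probability for group ", g)
    }
  }
  spec
}

#' Per-group latent process parameters
#'
#' @param onset_latency_ms Mean delay (ms) of the target ramp midpoint after
#'   verb onset.
#' @param target_bias Asymptotic target redraw probability.
#' @param start_prob Common redraw probability of all four AOIs at sentence
#'   onset (exploratory looking during/after the preview).
#' @param baseline Named redraw probabilities reached after the agent-based
#'   shift but before the verb-based shift: target, agent_related,
#'   action_related, unrelated (the remainder is the off-AOI background
#'   state).
#' @param agent_mid_ms,agent_scale_ms Midpoint and logistic scale of the
#'   agent-based ramp carrying all four conditions from `start_prob` to
#'   `baseline`.
#' @param agent_end Asymptotic agent-related redraw probability after the
#'   verb-based shift.
#' @param action_bump Height of the transient action-related bump.
#' @param bump_center_rel_ms,bump_sd_ms Centre (relative to verb onset) and
#'   SD of the Gaussian action bump.
#' @param ramp_scale_ms Logistic scale of the verb-based target/agent ramps.
#' @return A list of group parameters.
#' @export
group_params <- function(onset_latency_ms, target_bias,
                         start_prob = 0.12,
                         baseline = c(target = 0.15, agent_related = 0.22,
                                      action_related = 0.07,
                                      unrelated = 0.10),
                         agent_mid_ms = 650, agent_scale_ms = 150,
                         agent_end = 0.06, action_bump = 0.10,
                         bump_center_rel_ms = 900, bump_sd_ms = 300,
                         ramp_scale_ms = 150) {
  stopifnot(onset_latency_ms >= 0, target_bias > 0, target_bias < 1,
            start_prob > 0, 4 * start_prob < 1,
            all(baseline >= 0), sum(baseline) < 1)
  list(onset_latency_ms = onset_latency_ms, target_bias = target_bias,
       start_prob = start_prob, baseline = baseline,
       agent_mid_ms = agent_mid_ms, agent_scale_ms = agent_scale_ms,
       agent_end = agent_end,
       action_bump = action_bump, bump_center_rel_ms = bump_center_rel_ms,
       bump_sd_ms = bump_sd_ms, ramp_scale_ms = ramp_scale_ms)
}

#' Default score-link coefficients
#'
#' Linear coefficients mapping a participant's centred latency (ms) and
#' centred target bias to simulated AQ and CARS scores, plus Gaussian
#' noise. Group-level score means and SDs mirror the demographics of a
#' 45/52 autistic/NT cohort (AQ 89.5 vs 48.6; CARS 35.6, autistic group
#' only).
#'
#' @return A list of coefficients; pass to [cohort_spec()].
#' @export
default_score_link <- function() {
  list(
    aq_mean = c(autistic = 89.45, nt = 48.62),
    aq_latency = 0.05, aq_bias = -40, aq_noise_sd = 8,
    cars_mean = c(autistic = 35.63),
    cars_latency = 0.015, cars_bias = -15, cars_noise_sd = 2.5,
    subscale_noise_sd = 1.5
  )
}

#' Assemble one participant's latent-process parameters
#'
#' @param spec A [cohort_spec()].
#' @param group Group label.
#' @param latency,bias Realized participant parameters (defaults: the group
#'   means).
#' @return A list consumed by [redraw_probs()], [latent_marginal()] and
#'   [simulate_trial_gaze()].
#' @export
make_participant_params <- function(spec, group,
                                    latency = spec$groups[[group]]$onset_latency_ms,
                                    bias = spec$groups[[group]]$target_bias) {
  g <- spec$groups[[group]]
  # A participant's overall processing speed shifts the whole fixation
  # cascade: deviations from the group's mean latency move the agent-based
  # ramp by the same amount, while group differences act at the verb stage.
  g$agent_mid_ms <- g$agent_mid_ms + (latency - g$onset_latency_ms)
  lm <- timing_landmarks()
  c(g, list(latency = latency, bias = bias, group = group,
            verb_onset = lm[["verb_onset"]],
            min_dwell_bins = spec$min_dwell_bins,
            mean_dwell_bins = spec$mean_dwell_bins,
            bin_width_ms = spec$bin_width_ms,
            window_ms = spec$window_ms,
            jitter_sd_px = spec$jitter_sd_px,
            jitter_ar = spec$jitter_ar,
            eye_noise_px = spec$eye_noise_px,
            blink_rate_hz = spec$blink_rate_hz,
            blink_dur_range_ms = spec$blink_dur_range_ms))
}

#' Instantaneous redraw probabilities of the latent process
#'
#' Evaluates the five-state redraw distribution (target, agent-related,
#' action-related, unrelated, off-AOI) at the given times for one
#' participant.
#'
#' @param pp Participant parameters from [make_participant_params()].
#' @param t_ms Times in ms from sentence onset.
#' @return Matrix `length(t_ms)` x 5 with rows summing to 1.
#' @export
redraw_probs <- function(pp, t_ms) {
  m <- pp$verb_onset + pp$latency
  agent_ramp <- stats::plogis((t_ms - pp$agent_mid_ms) / pp$agent_scale_ms)
  verb_ramp <- stats::plogis((t_ms - m) / pp$ramp_scale_ms)
  b <- pp$baseline
  s0 <- pp$start_prob
  p_target <- s0 + (b[["target"]] - s0) * agent_ramp +
    (pp$bias - b[["target"]]) * verb_ramp
  p_agent <- s0 + (b[["agent_related"]] - s0) * agent_ramp +
    (pp$agent_end - b[["agent_related"]]) * verb_ramp
  bump_center <- pp$verb_onset + pp$bump_center_rel_ms
  p_action <- s0 + (b[["action_related"]] - s0) * agent_ramp +
    pp$action_bump * exp(-(t_ms - bump_center)^2 / (2 * pp$bump_sd_ms^2)) *
      (t_ms > pp$verb_onset)
  p_unrel <- s0 + (b[["unrelated"]] - s0) * agent_ramp
  p4 <- cbind(target = p_target, agent_related = p_agent,
              action_related = p_action, unrelated = p_unrel)
  cbind(p4, off = pmax(1 - rowSums(p4), 0))
}

#' Exact per-bin marginal occupancy of the latent dwell process
#'
#' Computes, by forward recursion over (state, dwell age), the probability
#' that each 50-ms bin is occupied by each state under the dwell-based
#' redraw process. This is the oracle that Monte-Carlo occupancy averages
#' converge to; because dwells persist, it is a smoothed, slightly lagged
#' version of the instantaneous redraw curves of [redraw_probs()].
#'
#' @param pp Participant parameters from [make_participant_params()].
#' @param n_bins Number of bins (default: the analysis window).
#' @return Matrix `n_bins` x 5 of occupancy probabilities (rows sum to 1).
#' @export
latent_marginal <- function(pp, n_bins = NULL) {
  bw <- pp$bin_width_ms
  if (is.null(n_bins)) n_bins <- diff(pp$window_ms) / bw
  centers <- (seq_len(n_bins) - 1) * bw + bw / 2
  pi_t <- redraw_probs(pp, centers)
  m <- pp$min_dwell_bins
  rho <- if (pp$mean_dwell_bins > m) {
    1 - 1 / (pp$mean_dwell_bins - m + 1)
  } else 0
  # f[s, a]: P(state s with dwell age a); age m means "age >= m".
  f <- matrix(0, 5, m)
  f[, 1] <- pi_t[1, ]
  out <- matrix(0, n_bins, 5, dimnames = list(NULL, colnames(pi_t)))
  out[1, ] <- rowSums(f)
  if (n_bins > 1) for (t in 2:n_bins) {
    # redraws are suppressed once a new minimum-length dwell no longer
    # fits before the window end (the sampler extends the last dwell)
    can_redraw <- t <= n_bins - m + 1
    fn <- matrix(0, 5, m)
    if (m > 1) {
      for (a in 1:(m - 1)) fn[, a + 1] <- fn[, a + 1] + f[, a]
      if (can_redraw) {
        fn[, m] <- fn[, m] + f[, m] * rho
        redraw_mass <- sum(f[, m]) * (1 - rho)
      } else {
        fn[, m] <- fn[, m] + f[, m]
        redraw_mass <- 0
      }
    } else {
      if (can_redraw) {
        fn[, 1] <- f[, 1] * rho
        redraw_mass <- sum(f[, 1]) * (1 - rho)
      } else {
        fn[, 1] <- f[, 1]
        redraw_mass <- 0
      }
    }
    if (redraw_mass > 0) fn[, 1] <- fn[, 1] + redraw_mass * pi_t[t, ]
    f <- fn
    out[t, ] <- rowSums(f)
  }
  out
}
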