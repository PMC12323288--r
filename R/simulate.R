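#' Simulate one trial's latent AOI state sequence
#'
#' Draws the dwell-based five-state sequence over the analysis bins for one
#' participant and trial. Uses the current RNG state.
#'
#' @param pp Participant parameters from [make_participant_params()].
#' @return Integer vector (one entry per bin) indexing the states
#'   target = 1, agent_related = 2, action_related = 3, unrelated = 4,
#'   off = 5.
#' @export
simulate_latent_states <- function(pp) {
  bw <- pp$bin_width_ms
  n_bins <- as.integer(diff(pp$window_ms) / bw)
  centers <- (seq_len(n_bins) - 1) * bw + bw / 2
  pi_t <- redraw_probs(pp, centers)
  m <- pp$min_dwell_bins
  rho <- if (pp$mean_dwell_bins > m) {
    1 - 1 / (pp$mean_dwell_bins - m + 1)
  } else 0
  states <- integer(n_bins)
  t <- 1L
  while (t <= n_bins) {
    s <- sample.int(5, 1, prob = pi_t[t, ])
    len <- m + if (rho > 0) stats::rgeom(1, 1 - rho) else 0L
    end <- t + as.integer(len) - 1L
    # no dwell shorter than m fits before the window end: extend to it
    if (n_bins - end < m) end <- n_bins
    states[t:min(end, n_bins)] <- s
    t <- min(end, n_bins) + 1L
  }
  states
}

# Screen coordinates of each latent state for one trial: AOI centres for the
# four conditions (per the trial's condition->position mapping), screen
# centre for the off state. Returns a 5 x 2 matrix.
state_coordinates <- function(design, layout, geometry) {
  conds <- vwp_conditions()
  cond_at_pos <- unlist(design[paste0("cond_pos", 1:4)], use.names = FALSE)
  xy <- matrix(NA_real_, 5, 2)
  for (p in 1:4) {
    s <- match(cond_at_pos[p], conds)
    xy[s, 1] <- layout$left[p] + layout$size[p] / 2
    xy[s, 2] <- layout$top[p] + layout$size[p] / 2
  }
  xy[5, ] <- c(geometry$width_px / 2, geometry$height_px / 2)
  xy
}

#' Simulate raw gaze samples for one trial
#'
#' Realizes a 120-Hz binocular gaze recording from the latent dwell process:
#' the gaze rests at the centre of the AOI occupied by the current latent
#' state (screen centre for the off state), perturbed by AR(1) drift-like
#' jitter and independent per-eye noise; blinks are inserted as
#' validity-flagged gaps with missing coordinates. Sample timestamps are
#' integer milliseconds.
#'
#' @param design One-row trial design (a row of [build_stimulus_set()]).
#' @param pp Participant parameters from [make_participant_params()].
#' @param layout An [aoi_layout()].
#' @param geometry A [screen_geometry()].
#' @param seed Optional integer seed; if `NULL` the current RNG is used.
#' @return A list with `gaze` (tibble: `t_ms`, `lx`, `ly`, `rx`, `ry`,
#'   `l_valid`, `r_valid`) and `states` (the latent per-bin state vector).
#' @export
simulate_trial_gaze <- function(design, pp, layout = aoi_layout(),
                                geometry = screen_geometry(), seed = NULL) {
  run <- function() {
    states <- simulate_latent_states(pp)
    xy <- state_coordinates(design, layout, geometry)
    bw <- pp$bin_width_ms
    dur <- diff(pp$window_ms)
    n <- as.integer(round(dur * geometry$hz / 1000))
    t_ms <- as.integer(round((seq_len(n) - 1) * 1000 / geometry$hz))
    bin_of_sample <- pmin(floor(t_ms / bw) + 1L, length(states))
    base <- xy[states[bin_of_sample], , drop = FALSE]
    if (pp$jitter_sd_px > 0) {
      innov_sd <- pp$jitter_sd_px * sqrt(1 - pp$jitter_ar^2)
      jx <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                     pp$jitter_ar, method = "recursive",
                                     init = stats::rnorm(1, 0, pp$jitter_sd_px)))
      jy <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                     pp$jitter_ar, method = "recursive",
                                     init = stats::rnorm(1, 0, pp$jitter_sd_px)))
    } else {
      jx <- jy <- numeric(n)
    }
    gx <- base[, 1] + jx
    gy <- base[, 2] + jy
    en <- pp$eye_noise_px
    lx <- gx + if (en > 0) stats::rnorm(n, 0, en) else 0
    ly <- gy + if (en > 0) stats::rnorm(n, 0, en) else 0
    rx <- gx + if (en > 0) stats::rnorm(n, 0, en) else 0
    ry <- gy + if (en > 0) stats::rnorm(n, 0, en) else 0
    lx <- pmin(pmax(lx, 0), geometry$width_px)
    rx <- pmin(pmax(rx, 0), geometry$width_px)
    ly <- pmin(pmax(ly, 0), geometry$height_px)
    ry <- pmin(pmax(ry, 0), geometry$height_px)
    l_valid <- r_valid <- rep(1L, n)
    if (pp$blink_rate_hz > 0) {
      n_blinks <- stats::rpois(1, pp$blink_rate_hz * dur / 1000)
      if (n_blinks > 0) {
        bl_dur <- stats::runif(n_blinks, pp$blink_dur_range_ms[1],
                               pp$blink_dur_range_ms[2])
        bl_start <- stats::runif(n_blinks, 0, dur - bl_dur)
        for (b in seq_len(n_blinks)) {
          hit <- t_ms >= bl_start[b] & t_ms < bl_start[b] + bl_dur[b]
          l_valid[hit] <- 0L
          r_valid[hit] <- 0L
        }
      }
    }
    lx[l_valid == 0L] <- NA_real_; ly[l_valid == 0L] <- NA_real_
    rx[r_valid == 0L] <- NA_real_; ry[r_valid == 0L] <- NA_real_
    list(
      gaze = tibble::tibble(t_ms = t_ms, lx = lx, ly = ly, rx = rx, ry = ry,
                            l_valid = l_valid, r_valid = r_valid),
      states = states
    )
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Simulate a full two-group cohort
#'
#' Generates the complete synthetic dataset for a cohort: per-participant
#' pseudo-randomized trial orders over the counterbalanced stimulus set,
#' raw gaze tables (or, with `level = "tensor"`, the latent occupancy
#' tensor directly, skipping the sample-level realization), a score table
#' whose AQ/CARS values are linked to each participant's realized latency
#' and bias, per-trial behavioral responses, and the ground truth.
#'
#' @details Scores are generated as
#' `AQ = group mean + b_lat * (latency - group mean latency) +
#'  b_bias * (bias - group bias) + noise`, with five AQ subscales drawn as
#' equal shares of the total plus noise and then summed back so the total
#' always equals the subscale sum. CARS is generated for the autistic-like
#' first group only, mirroring score tables in which the clinician-rated
#' scale is administered to one group.
#'
#' @param spec A [cohort_spec()].
#' @param level `"gaze"` (full sample-level realization) or `"tensor"`
#'   (latent per-bin occupancy only; much faster, identical downstream
#'   statistics contract).
#' @param lex Lexicon used to build the stimulus set.
#' @return A list with elements `gaze` (tibble, `level = "gaze"` only),
#'   `tensor` (the latent occupancy tensor, always present: with
#'   `level = "gaze"` it is the ground-truth occupancy the preprocessing
#'   stage should recover), `designs` (per-participant ordered designs),
#'   `scores`, `responses`,
#'   `ground_truth` (per-participant realized latency/bias and the
#'   between-group true latency shift) and the `spec`.
#' @export
simulate_cohort <- function(spec, level = c("gaze", "tensor"),
                            lex = default_lexicon()) {
  stopifnot(inherits(spec, "vwp_cohort_spec"))
  level <- match.arg(level)
  if (any(spec$n_per_group < 2)) stop("n_per_group must be >= 2")
  designs <- build_stimulus_set(lex)
  if (spec$n_trials < nrow(designs)) {
    designs <- designs[seq_len(spec$n_trials), ]
  } else if (spec$n_trials > nrow(designs)) {
    stop("n_trials exceeds the stimulus set (", nrow(designs), " trials)")
  }
  group_names <- names(spec$n_per_group)
  prefix <- substr(group_names, 1, 1)
  if (prefix[1] == prefix[2]) prefix <- c("g1_", "g2_")
  n_bins <- as.integer(diff(spec$window_ms) / spec$bin_width_ms)
  conds <- vwp_conditions()

  withr::with_seed(spec$seed, {
    gaze_list <- list(); tensor_list <- list(); design_list <- list()
    score_list <- list(); resp_list <- list(); truth_list <- list()
    k <- 0L
    for (gi in seq_along(group_names)) {
      g <- group_names[gi]
      gp <- spec$groups[[g]]
      for (i in seq_len(spec$n_per_group[[g]])) {
        k <- k + 1L
        pid <- sprintf("%s%03d", prefix[gi], i)
        latency <- clamp(stats::rnorm(1, gp$onset_latency_ms,
                                      spec$latency_sd_ms),
                         spec$latency_range)
        bias <- clamp(stats::rnorm(1, gp$target_bias, spec$bias_sd),
                      spec$bias_range)
        pp <- make_participant_params(spec, g, latency = latency,
                                      bias = bias)
        ord <- pseudo_randomize(designs,
                                seed = sample.int(.Machine$integer.max, 1))
        ord$presentation_order <- seq_len(nrow(ord))
        ord$participant_id <- pid
        design_list[[k]] <- ord

        states_mat <- matrix(0L, nrow(ord), n_bins)
        if (level == "gaze") {
          trial_gaze <- vector("list", nrow(ord))
          for (tr in seq_len(nrow(ord))) {
            sim <- simulate_trial_gaze(ord[tr, ], pp, spec$layout,
                                       spec$geometry)
            states_mat[tr, ] <- sim$states
            gz <- sim$gaze
            gz$participant_id <- pid
            gz$trial_id <- ord$trial_id[tr]
            trial_gaze[[tr]] <- gz
          }
          gaze_list[[k]] <- dplyr::bind_rows(trial_gaze)
        } else {
          for (tr in seq_len(nrow(ord))) {
            states_mat[tr, ] <- simulate_latent_states(pp)
          }
        }
        tensor_list[[k]] <- states_to_tensor(states_mat, pid, g,
                                             ord$trial_id, n_bins)

        sl <- spec$score_link
        lat_c <- latency - gp$onset_latency_ms
        bias_c <- bias - gp$target_bias
        aq_total <- sl$aq_mean[[g]] + sl$aq_latency * lat_c +
          sl$aq_bias * bias_c + stats::rnorm(1, 0, sl$aq_noise_sd)
        subs <- aq_total / 5 + stats::rnorm(5, 0, sl$subscale_noise_sd)
        aq_total <- sum(subs)
        cars <- if (g %in% names(sl$cars_mean)) {
          sl$cars_mean[[g]] + sl$cars_latency * lat_c +
            sl$cars_bias * bias_c + stats::rnorm(1, 0, sl$cars_noise_sd)
        } else NA_real_
        score_list[[k]] <- tibble::tibble(
          participant_id = pid, group = g,
          age = round(stats::runif(1, 3.5, 7.5), 2),
          verbal_iq = round(stats::rnorm(1, 107, 14)),
          cars_total = cars, aq_total = aq_total,
          aq_social_skills = subs[1], aq_attention_switching = subs[2],
          aq_attention_to_detail = subs[3], aq_communication = subs[4],
          aq_imagination = subs[5]
        )
        u <- stats::rnorm(1, 0, spec$accuracy_re_sd)
        p_corr <- stats::plogis(spec$accuracy_logit[[g]] + u)
        resp_list[[k]] <- tibble::tibble(
          participant_id = pid, group = g, trial_id = ord$trial_id,
          correct = as.integer(stats::runif(nrow(ord)) < p_corr)
        )
        truth_list[[k]] <- tibble::tibble(
          participant_id = pid, group = g,
          latency_ms = latency, bias = bias
        )
      }
    }
    truth <- dplyr::bind_rows(truth_list)
    lat_means <- vapply(spec$groups, function(x) x$onset_latency_ms, 0)
    out <- list(
      designs = dplyr::bind_rows(design_list),
      scores = dplyr::bind_rows(score_list),
      responses = dplyr::bind_rows(resp_list),
      tensor = dplyr::bind_rows(tensor_list),
      ground_truth = list(
        participants = truth,
        group_shift_ms = unname(lat_means[1] - lat_means[2])
      ),
      spec = spec
    )
    if (level == "gaze") out$gaze <- dplyr::bind_rows(gaze_list)
    out
  })
}

clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

# Convert a trials x bins latent state matrix into the wide occupancy
# tensor format (one row per trial x bin, binary condition columns).
states_to_tensor <- function(states_mat, pid, group, trial_ids, n_bins) {
  n_tr <- nrow(states_mat)
  s <- as.vector(t(states_mat))  # trial-major, bin fastest
  tibble::tibble(
    participant_id = pid, group = group,
    trial_id = rep(trial_ids, each = n_bins),
    bin = rep(0:(n_bins - 1), n_tr),
    target = as.integer(s == 1L),
    agent_related = as.integer(s == 2L),
    action_related = as.integer(s == 3L),
    unrelated = as.integer(s == 4L)
  )
}
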