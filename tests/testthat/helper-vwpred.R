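# Shared fixtures for the test suite. Everything is built in code.

# Group parameters with no condition effect: all four AOIs share one
# constant redraw probability, so target vs unrelated differences are
# exchangeable in sign.
null_group_params <- function(p = 0.1) {
  group_params(onset_latency_ms = 900, target_bias = p, start_prob = p,
               baseline = c(target = p, agent_related = p,
                            action_related = p, unrelated = p),
               agent_end = p, action_bump = 0)
}

# A score link whose group names match arbitrary two-group specs.
test_score_link <- function(groups) {
  sl <- default_score_link()
  sl$aq_mean <- stats::setNames(c(89.45, 48.62), groups)
  sl$cars_mean <- stats::setNames(35.63, groups[1])
  sl
}

# Small two-group cohort spec for fast tests.
small_spec <- function(n1 = 4, n2 = 4, seed = 1, ...) {
  cohort_spec(n_per_group = c(autistic = n1, nt = n2), seed = seed, ...)
}

# Cohort spec with identically parameterized groups except for a pure
# latency shift (ms) of the first group: both the verb-stage latency and
# the agent ramp midpoint move together, so the first group's latent
# curves are an exact time translation of the second group's and the true
# divergence shift equals shift_ms. The wide latency range avoids
# asymmetric truncation of the shifted group's participant draws.
shift_spec <- function(shift_ms, n1 = 45, n2 = 52, seed = 1,
                       base_latency = 850, bias = 0.55, ...) {
  cohort_spec(
    n_per_group = c(autistic = n1, nt = n2),
    groups = list(
      autistic = group_params(onset_latency_ms = base_latency + shift_ms,
                              agent_mid_ms = 650 + shift_ms,
                              target_bias = bias),
      nt = group_params(onset_latency_ms = base_latency,
                        target_bias = bias)
    ),
    latency_range = c(100, 1600),
    seed = seed, ...
  )
}

# Build a one-trial gaze table from a piecewise-constant path:
# segments is a data.frame with columns from_ms, to_ms, x, y, valid.
# Samples at 120 Hz with integer-ms timestamps; both eyes identical.
make_gaze <- function(segments, hz = 120, trial_ms = 2500) {
  n <- round(trial_ms * hz / 1000)
  t_ms <- as.integer(round((seq_len(n) - 1) * 1000 / hz))
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); valid <- rep(0L, n)
  for (i in seq_len(nrow(segments))) {
    hit <- t_ms >= segments$from_ms[i] & t_ms < segments$to_ms[i]
    x[hit] <- segments$x[i]
    y[hit] <- segments$y[i]
    valid[hit] <- as.integer(segments$valid[i])
  }
  x[valid == 0L] <- NA_real_
  y[valid == 0L] <- NA_real_
  tibble::tibble(t_ms = t_ms, lx = x, ly = y, rx = x, ry = y,
                 l_valid = valid, r_valid = valid)
}

# Wide occupancy tensor built directly from per-participant 0/1 matrices:
# mats is a named list group -> list(participant matrices trials x bins)
# for the given condition columns.
make_tensor <- function(target, agent = NULL, action = NULL,
                        unrelated = NULL, group = "g", pid_prefix = "p") {
  n_bins <- ncol(target[[1]])
  zeros <- function(m) if (is.null(m)) lapply(target, function(x) x * 0L) else m
  agent <- zeros(agent); action <- zeros(action); unrelated <- zeros(unrelated)
  out <- list()
  for (i in seq_along(target)) {
    n_tr <- nrow(target[[i]])
    out[[i]] <- tibble::tibble(
      participant_id = sprintf("%s%03d", pid_prefix, i),
      group = group,
      trial_id = rep(seq_len(n_tr), each = n_bins),
      bin = rep(0:(n_bins - 1), n_tr),
      target = as.integer(t(target[[i]])),
      agent_related = as.integer(t(agent[[i]])),
      action_related = as.integer(t(action[[i]])),
      unrelated = as.integer(t(unrelated[[i]]))
    )
  }
  dplyr::bind_rows(out)
}

# Exhaustive sign-flip null of the max cluster sum for a small paired
# difference matrix (participants x bins): independent oracle for the
# permutation test, enumerating all 2^n assignments.
exact_perm_p <- function(d, sum_t_obs, alpha = 0.05) {
  n <- nrow(d)
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  maxima <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(code, 2^(0:(n - 1))) > 0, -1, 1)
    ds <- d * signs
    mu <- colMeans(ds)
    sdv <- apply(ds, 2, stats::sd)
    tt <- ifelse(sdv < 1e-12, 0, mu / (sdv / sqrt(n)))
    lab <- ifelse(abs(tt) > crit, sign(tt), 0)
    r <- rle(lab)
    keep <- r$values != 0 & r$lengths >= 2
    if (any(keep)) {
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      maxima[code + 1] <- max(vapply(which(keep), function(i) {
        abs(sum(tt[starts[i]:ends[i]]))
      }, 0))
    }
  }
  mean(maxima >= abs(sum_t_obs))
}

# Simulate a log-ratio-style series directly from the growth-curve
# generative model (known fixed effects, random intercepts, residual
# noise). Returns a series tibble suitable for fit_growth_model().
simulate_gca_series <- function(n_per_group = c(a = 16, b = 16),
                                n_trials = 12, n_bins = 50,
                                beta = c(intercept = 0.13, ot1 = 0.95,
                                         ot2 = 0.28),
                                group_beta = c(group = 0, ot1_group = 0),
                                sd_participant = 0.08, sd_trial = 0.03,
                                sd_resid = 0.5) {
  basis <- orthogonal_time_basis(n_bins, 2)
  rows <- list()
  pid <- 0
  trial_fx <- stats::rnorm(n_trials, 0, sd_trial)  # shared item effects
  for (g in names(n_per_group)) {
    gi <- as.integer(g == names(n_per_group)[1])  # first group = treatment
    for (i in seq_len(n_per_group[[g]])) {
      pid <- pid + 1
      u <- stats::rnorm(1, 0, sd_participant)
      for (tr in seq_len(n_trials)) {
        mu <- beta[["intercept"]] + beta[["ot1"]] * basis$ot1 +
          beta[["ot2"]] * basis$ot2 +
          gi * (group_beta[["group"]] +
                  group_beta[["ot1_group"]] * basis$ot1) +
          u + trial_fx[tr]
        rows[[length(rows) + 1]] <- tibble::tibble(
          participant_id = sprintf("p%03d", pid), group = g,
          trial_id = tr, bin = basis$bin,
          value = mu + stats::rnorm(n_bins, 0, sd_resid)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
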