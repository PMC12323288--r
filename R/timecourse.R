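#' Fixation-proportion time courses
#'
#' Per group, condition and bin: the mean over participants of each
#' participant's trial-averaged occupancy, with a normal-approximation 95%
#' CI over participants.
#'
#' @param tensor Occupancy tensor (see [preprocess_cohort()]).
#' @return Tibble `group`, `condition`, `bin`, `time_ms` (bin centre),
#'   `prop`, `ci_lo`, `ci_hi`, `n`.
#' @export
proportion_curves <- function(tensor) {
  groups <- unique(tensor$group)
  if (any(is.na(groups))) stop("tensor has unlabelled groups")
  out <- list()
  for (g in groups) {
    for (cond in vwp_conditions()) {
      m <- prop_matrix(tensor, cond, g)
      n <- nrow(m)
      if (n < 1) stop("empty group ", g)
      mu <- colMeans(m)
      se <- apply(m, 2, stats::sd) / sqrt(n)
      bins <- as.integer(colnames(m))
      out[[length(out) + 1]] <- tibble::tibble(
        group = g, condition = cond, bin = bins,
        time_ms = bins * 50 + 25,
        prop = unname(mu),
        ci_lo = unname(mu - 1.96 * se), ci_hi = unname(mu + 1.96 * se),
        n = n
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Log-gaze proportion ratio series
#'
#' The bias of target over unrelated looking,
#' `log((target + 0.5) / (unrelated + 0.5))` (natural log), computed either
#' per trial on the binary occupancies (default; the response used by the
#' growth-curve model with trial random intercepts) or per participant on
#' trial-averaged proportions. The 0.5 offsets keep the ratio defined for
#' zero occupancy; the measure is exactly antisymmetric under swapping the
#' two conditions.
#'
#' @param tensor Occupancy tensor.
#' @param level `"trial"` or `"participant"`.
#' @param num,den Condition columns forming the ratio.
#' @return Tibble with `participant_id`, `group`, `bin`, `value` and, at
#'   trial level, `trial_id`.
#' @export
log_ratio_series <- function(tensor, level = c("trial", "participant"),
                             num = "target", den = "unrelated") {
  level <- match.arg(level)
  if (!all(c(num, den) %in% names(tensor))) {
    stop("tensor lacks the ", num, "/", den, " condition columns")
  }
  if (level == "trial") {
    tibble::tibble(
      participant_id = tensor$participant_id, group = tensor$group,
      trial_id = tensor$trial_id, bin = tensor$bin,
      value = log((tensor[[num]] + 0.5) / (tensor[[den]] + 0.5))
    )
  } else {
    agg <- tensor |>
      dplyr::group_by(.data$participant_id, .data$group, .data$bin) |>
      dplyr::summarise(num_p = mean(.data[[num]]),
                       den_p = mean(.data[[den]]), .groups = "drop")
    tibble::tibble(
      participant_id = agg$participant_id, group = agg$group,
      bin = agg$bin,
      value = log((agg$num_p + 0.5) / (agg$den_p + 0.5))
    )
  }
}

#' Per-participant prediction-efficiency indices
#'
#' Two indices per participant: the log-ratio index (mean log-gaze
#' proportion ratio over the bins lying fully inside the prediction window,
#' agent onset to patient onset) and the individual divergence point (start
#' of the first run of at least `run_bins` consecutive bins in which the
#' participant's trial-averaged target proportion strictly exceeds the
#' agent-related proportion, searched from verb onset; `NA` when no such
#' run exists).
#'
#' @param tensor Occupancy tensor.
#' @param series Optional precomputed trial-level [log_ratio_series()].
#' @param pred_window_ms Prediction window for the log-ratio index,
#'   default `c(0, 1300)`.
#' @param dp_window_ms Search window for the individual divergence point,
#'   default `c(750, 2500)`.
#' @param run_bins Sustained-run length, default 4 (200 ms).
#' @param bin_width_ms Bin width.
#' @return Tibble `participant_id`, `group`, `log_ratio_index`,
#'   `individual_dp_ms`, `dp_run_bins`.
#' @export
participant_indices <- function(tensor, series = NULL,
                                pred_window_ms = c(0, 1300),
                                dp_window_ms = c(750, 2500),
                                run_bins = 4, bin_width_ms = 50) {
  if (is.null(series)) series <- log_ratio_series(tensor, "trial")
  keep <- series$bin * bin_width_ms >= pred_window_ms[1] &
    (series$bin + 1) * bin_width_ms <= pred_window_ms[2]
  idx <- series[keep, ] |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(log_ratio_index = mean(.data$value), .groups = "drop")

  tgt <- prop_matrix(tensor, "target")
  agt <- prop_matrix(tensor, "agent_related")
  bins <- as.integer(colnames(tgt))
  in_win <- bins * bin_width_ms >= dp_window_ms[1] &
    bins * bin_width_ms < dp_window_ms[2]
  dp <- vapply(rownames(tgt), function(pid) {
    above <- tgt[pid, in_win] > agt[pid, in_win]
    first_run_start(above, run_bins, bins[in_win]) * bin_width_ms
  }, 0)
  idx$individual_dp_ms <- unname(dp[match(idx$participant_id,
                                          rownames(tgt))])
  idx$dp_run_bins <- run_bins
  idx
}

# Start bin of the first run of >= k consecutive TRUE; NA_real_ if none.
first_run_start <- function(flags, k, bin_ids) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= k)
  if (length(hit) == 0) return(NA_real_)
  bin_ids[starts[hit[1]]]
}
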