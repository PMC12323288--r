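#' I-VT fixation classification parameters
#'
#' @param velocity_threshold_deg_s Angular velocity below which a sample is
#'   classified as belonging to a fixation. 30 deg/s is the conventional
#'   I-VT default.
#' @param velocity_window_ms Length of the symmetric window over which
#'   sample velocity is computed.
#' @param max_gap_ms Maximum invalid-data gap (per eye) filled by linear
#'   interpolation before classification.
#' @param merge_max_gap_ms,merge_max_angle_deg Adjacent fixations separated
#'   by at most this interval *and* angular distance are merged
#'   (conjunctive criterion).
#' @param min_duration_ms Fixations shorter than this are discarded.
#' @return A list of filter parameters.
#' @export
ivt_params <- function(velocity_threshold_deg_s = 30,
                       velocity_window_ms = 20,
                       max_gap_ms = 75,
                       merge_max_gap_ms = 75,
                       merge_max_angle_deg = 0.5,
                       min_duration_ms = 100) {
  stopifnot(velocity_threshold_deg_s > 0, velocity_window_ms > 0,
            max_gap_ms >= 0, merge_max_gap_ms >= 0,
            merge_max_angle_deg >= 0, min_duration_ms >= 0)
  list(velocity_threshold_deg_s = velocity_threshold_deg_s,
       velocity_window_ms = velocity_window_ms,
       max_gap_ms = max_gap_ms,
       merge_max_gap_ms = merge_max_gap_ms,
       merge_max_angle_deg = merge_max_angle_deg,
       min_duration_ms = min_duration_ms)
}

# Linear interpolation of invalid gaps no longer than max_gap_ms, one eye.
# A gap is a run of invalid samples bounded by valid samples on both sides;
# its length is the time between the bounding valid samples.
interpolate_gaps <- function(t, x, y, valid, max_gap_ms) {
  v <- which(valid == 1 & !is.na(x))
  if (length(v) < 2) return(list(x = x, y = y, valid = valid))
  r <- rle(valid == 1 & !is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$values)) {
    if (r$values[i]) next
    if (i == 1 || i == length(r$values)) next  # unbounded gap
    a <- starts[i] - 1L; b <- ends[i] + 1L
    if (t[b] - t[a] > max_gap_ms) next
    idx <- starts[i]:ends[i]
    w <- (t[idx] - t[a]) / (t[b] - t[a])
    x[idx] <- x[a] + w * (x[b] - x[a])
    y[idx] <- y[a] + w * (y[b] - y[a])
    valid[idx] <- 1L
  }
  list(x = x, y = y, valid = valid)
}

# Sample angular velocity (deg/s) over a symmetric time window. For sample
# i the velocity uses the nearest samples at least window/2 before and
# after; edge samples shrink the window. NA where either endpoint is
# missing.
sample_velocity <- function(t, x, y, geometry, window_ms) {
  n <- length(t)
  half <- window_ms / 2
  # indices of window endpoints: t is (near-)regular, so a fixed sample
  # offset suffices.
  step <- max(1L, as.integer(round(half / geometry$sample_period_ms)))
  i1 <- pmax(seq_len(n) - step, 1L)
  i2 <- pmin(seq_len(n) + step, n)
  dt <- (t[i2] - t[i1]) / 1000
  dpx <- sqrt((x[i2] - x[i1])^2 + (y[i2] - y[i1])^2)
  v <- px_to_deg(dpx, geometry) / dt
  v[i2 == i1] <- NA_real_
  v
}

#' Detect fixations with an I-VT velocity filter
#'
#' Applies, in order: (1) per-eye linear interpolation of invalid gaps no
#' longer than `max_gap_ms`; (2) binocular averaging where both eyes are
#' valid, falling back to the single valid eye; (3) velocity-threshold
#' classification (samples with angular velocity at or below the threshold
#' form fixation candidates); (4) merging of adjacent fixations separated by
#' at most `merge_max_gap_ms` and `merge_max_angle_deg` (both criteria must
#' hold); (5) removal of fixations shorter than `min_duration_ms`.
#'
#' A fixation spans from its first sample to the timestamp of the first
#' sample after its last (or last sample + one sample period at the trial
#' end), so an uninterrupted full-trial fixation has the full trial
#' duration.
#'
#' @param gaze Tibble of one trial's samples: `t_ms`, `lx`, `ly`, `rx`,
#'   `ry`, `l_valid`, `r_valid`.
#' @param geometry A [screen_geometry()]; required, since the merge-angle
#'   and velocity criteria are defined in degrees.
#' @param params An [ivt_params()] list.
#' @return Tibble of fixations: `onset_ms`, `offset_ms`, `duration_ms`,
#'   `x`, `y` (centroid), `n_samples`, `source` (`binocular`, `left_only`,
#'   `right_only`, or `mixed` after merging across sources).
#' @export
detect_fixations <- function(gaze, geometry = screen_geometry(),
                             params = ivt_params()) {
  if (is.null(geometry)) stop("geometry is required (angle criteria)")
  t <- gaze$t_ms
  le <- interpolate_gaps(t, gaze$lx, gaze$ly, gaze$l_valid, params$max_gap_ms)
  re <- interpolate_gaps(t, gaze$rx, gaze$ry, gaze$r_valid, params$max_gap_ms)
  both <- le$valid == 1 & re$valid == 1
  lonly <- le$valid == 1 & re$valid != 1
  ronly <- re$valid == 1 & le$valid != 1
  x <- ifelse(both, (le$x + re$x) / 2, ifelse(lonly, le$x, re$x))
  y <- ifelse(both, (le$y + re$y) / 2, ifelse(lonly, le$y, re$y))
  ok <- both | lonly | ronly
  x[!ok] <- NA_real_; y[!ok] <- NA_real_
  src <- ifelse(both, "binocular", ifelse(lonly, "left_only",
                                          ifelse(ronly, "right_only", NA)))
  v <- sample_velocity(t, x, y, geometry, params$velocity_window_ms)
  cand <- ok & !is.na(v) & v <= params$velocity_threshold_deg_s
  cand[is.na(cand)] <- FALSE
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  fix <- list()
  period <- geometry$sample_period_ms
  n <- length(t)
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    # a run ending at the last sample extends one (rounded) sample period,
    # so an uninterrupted trial-long fixation spans the whole trial
    offset <- if (ends[i] < n) t[ends[i] + 1L] else t[n] + round(period)
    fsrc <- unique(src[idx])
    fix[[length(fix) + 1]] <- tibble::tibble(
      onset_ms = t[starts[i]], offset_ms = offset,
      x = mean(x[idx]), y = mean(y[idx]),
      n_samples = length(idx),
      source = if (length(fsrc) == 1) fsrc else "mixed"
    )
  }
  if (length(fix) == 0) {
    return(tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                          duration_ms = numeric(), x = numeric(),
                          y = numeric(), n_samples = integer(),
                          source = character()))
  }
  fx <- dplyr::bind_rows(fix)
  fx <- merge_fixations(fx, geometry, params$merge_max_gap_ms,
                        params$merge_max_angle_deg)
  fx$duration_ms <- fx$offset_ms - fx$onset_ms
  fx <- fx[fx$duration_ms >= params$min_duration_ms, ]
  fx[, c("onset_ms", "offset_ms", "duration_ms", "x", "y", "n_samples",
         "source")]
}

#' Merge adjacent fixations
#'
#' Repeatedly merges consecutive fixations whose temporal gap is at most
#' `max_gap_ms` and whose centroids are at most `max_angle_deg` apart, until
#' no further merge applies (so the operation is idempotent). Centroids of
#' merged fixations are sample-count-weighted means.
#'
#' @param fx Fixation tibble (as from [detect_fixations()], pre-merge).
#' @param geometry A [screen_geometry()].
#' @param max_gap_ms,max_angle_deg Conjunctive merge criteria.
#' @return Merged fixation tibble.
#' @export
merge_fixations <- function(fx, geometry, max_gap_ms = 75,
                            max_angle_deg = 0.5) {
  repeat {
    if (nrow(fx) < 2) return(fx)
    merged_any <- FALSE
    out <- fx[1, ]
    for (i in 2:nrow(fx)) {
      last <- nrow(out)
      gap <- fx$onset_ms[i] - out$offset_ms[last]
      ang <- px_to_deg(sqrt((fx$x[i] - out$x[last])^2 +
                              (fx$y[i] - out$y[last])^2), geometry)
      if (gap <= max_gap_ms && ang <= max_angle_deg) {
        w1 <- out$n_samples[last]; w2 <- fx$n_samples[i]
        out$x[last] <- (out$x[last] * w1 + fx$x[i] * w2) / (w1 + w2)
        out$y[last] <- (out$y[last] * w1 + fx$y[i] * w2) / (w1 + w2)
        out$offset_ms[last] <- fx$offset_ms[i]
        out$n_samples[last] <- w1 + w2
        if (out$source[last] != fx$source[i]) out$source[last] <- "mixed"
        merged_any <- TRUE
      } else {
        out <- dplyr::bind_rows(out, fx[i, ])
      }
    }
    fx <- out
    if (!merged_any) break
  }
  fx
}
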