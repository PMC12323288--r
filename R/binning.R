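#' Assign fixations to AOI conditions
#'
#' Labels each fixation with the condition of the AOI containing its
#' centroid, given the trial's condition-to-position mapping. Regions are
#' half-open (left/top edge inclusive, right/bottom exclusive); a centroid
#' outside every region gets `NA`.
#'
#' @param fx Fixation tibble from [detect_fixations()].
#' @param design One-row trial design (condition at each position).
#' @param layout An [aoi_layout()].
#' @return `fx` with a `condition` column.
#' @export
assign_aoi <- function(fx, design, layout) {
  cond_at_pos <- unlist(design[paste0("cond_pos", 1:4)], use.names = FALSE)
  cond <- rep(NA_character_, nrow(fx))
  for (p in 1:4) {
    inside <- fx$x >= layout$left[p] & fx$x < layout$left[p] + layout$size[p] &
      fx$y >= layout$top[p] & fx$y < layout$top[p] + layout$size[p]
    cond[inside] <- cond_at_pos[p]
  }
  fx$condition <- cond
  fx
}

#' Bin labelled fixations into binary AOI occupancy
#'
#' Codes condition `c` as 1 in bin `b` (bin `b` covers
#' `[b * width, (b + 1) * width)` ms, 0-based) whenever some fixation
#' labelled `c` overlaps the bin by more than `min_overlap_ms`.
#'
#' @param fx Labelled fixation tibble from [assign_aoi()].
#' @param window_ms Analysis window, default `c(0, 2500)`.
#' @param bin_width_ms Bin width; must divide the window length.
#' @param min_overlap_ms Minimal overlap for a bin to count (default 0:
#'   any positive overlap).
#' @return Tibble with `bin` (0-based) and one binary column per condition.
#' @export
bin_fixations <- function(fx, window_ms = c(0, 2500), bin_width_ms = 50,
                          min_overlap_ms = 0) {
  len <- diff(window_ms)
  if (len %% bin_width_ms != 0) {
    stop("bin width ", bin_width_ms, " does not divide the window length ",
         len)
  }
  n_bins <- len / bin_width_ms
  conds <- vwp_conditions()
  occ <- matrix(0L, n_bins, length(conds), dimnames = list(NULL, conds))
  keep <- !is.na(fx$condition) & fx$condition %in% conds
  edges <- window_ms[1] + (0:n_bins) * bin_width_ms
  for (i in which(keep)) {
    lo <- pmax(fx$onset_ms[i], edges[-length(edges)])
    hi <- pmin(fx$offset_ms[i], edges[-1])
    hit <- (hi - lo) > min_overlap_ms
    occ[hit, fx$condition[i]] <- 1L
  }
  dplyr::bind_cols(tibble::tibble(bin = 0:(n_bins - 1)),
                   tibble::as_tibble(occ))
}

#' Preprocess a cohort of raw gaze into the binned fixation tensor
#'
#' Runs the full preprocessing chain (I-VT fixation detection, AOI
#' assignment, binary binning) for every participant and trial, producing
#' the occupancy tensor that all statistical stages consume.
#'
#' @param gaze Combined gaze tibble with `participant_id`, `trial_id` and
#'   the sample columns of [simulate_trial_gaze()] / [read_gaze_table()].
#' @param designs Per-participant designs (rows of [build_stimulus_set()]
#'   with `participant_id`), or a single shared design table.
#' @param groups Optional tibble `participant_id`, `group` used to label
#'   the tensor (taken from `designs` columns or `scores` tables
#'   otherwise).
#' @param geometry,layout,params Geometry, AOI layout and [ivt_params()].
#' @param window_ms,bin_width_ms Analysis binning.
#' @return The occupancy tensor: tibble `participant_id`, `group`,
#'   `trial_id`, `bin`, and a binary column per condition.
#' @export
preprocess_cohort <- function(gaze, designs, groups = NULL,
                              geometry = screen_geometry(),
                              layout = aoi_layout(geometry = geometry),
                              params = ivt_params(),
                              window_ms = c(0, 2500), bin_width_ms = 50) {
  key <- paste(designs$participant_id, designs$trial_id)
  design_ix <- stats::setNames(seq_len(nrow(designs)), key)
  out <- gaze |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::group_map(function(g, k) {
      ix <- design_ix[[paste(k$participant_id, k$trial_id)]]
      if (is.null(ix)) {
        stop("no design row for participant ", k$participant_id,
             " trial ", k$trial_id)
      }
      fx <- detect_fixations(g, geometry, params)
      fx <- assign_aoi(fx, designs[ix, ], layout)
      occ <- bin_fixations(fx, window_ms, bin_width_ms)
      occ$participant_id <- k$participant_id
      occ$trial_id <- k$trial_id
      occ
    }) |>
    dplyr::bind_rows()
  if (is.null(groups) && "group" %in% names(designs)) {
    groups <- dplyr::distinct(designs, .data$participant_id, .data$group)
  }
  if (!is.null(groups)) {
    out <- dplyr::left_join(out, groups, by = "participant_id")
  } else {
    out$group <- NA_character_
  }
  dplyr::select(out, "participant_id", "group", "trial_id", "bin",
                dplyr::all_of(vwp_conditions()))
}

#' Participant-level trial-averaged proportion matrix
#'
#' Averages the binary occupancy of one condition over trials, per
#' participant and bin — the participant-level fixation-proportion series
#' used by the cluster permutation and divergence analyses.
#'
#' @param tensor Occupancy tensor (see [preprocess_cohort()]).
#' @param condition Condition column to average.
#' @param group Optional group label to filter on.
#' @return Matrix participants x bins, with participant ids as row names;
#'   columns ordered by bin.
#' @export
prop_matrix <- function(tensor, condition, group = NULL) {
  if (!is.null(group)) tensor <- tensor[tensor$group %in% group, ]
  if (nrow(tensor) == 0) stop("empty group: no tensor rows selected")
  agg <- stats::aggregate(tensor[[condition]],
                          list(participant_id = tensor$participant_id,
                               bin = tensor$bin), mean)
  pids <- sort(unique(agg$participant_id))
  bins <- sort(unique(agg$bin))
  m <- matrix(NA_real_, length(pids), length(bins),
              dimnames = list(pids, bins))
  m[cbind(match(agg$participant_id, pids), match(agg$bin, bins))] <- agg$x
  m
}
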