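#' Write and read gaze-sample tables
#'
#' Gaze tables use a single canonical long TSV dialect with columns
#' `participant_id`, `trial_id`, `t_ms` (integer ms from sentence onset),
#' `lx`, `ly`, `rx`, `ry` (screen px; empty when the eye is invalid) and
#' `l_valid`, `r_valid` (0/1). `read_gaze_table()` validates the schema:
#' missing columns and non-monotone timestamps are errors (naming the
#' offending trial); rows whose coordinates fall outside the screen while
#' flagged valid are retained but re-flagged invalid.
#'
#' @param gaze Gaze tibble.
#' @param path File path (TSV).
#' @param geometry A [screen_geometry()] used for bounds checking.
#' @param col_map Optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(t_ms = "timestamp")`.
#' @return `read_gaze_table()` returns the validated tibble;
#'   `write_gaze_table()` returns `path` invisibly.
#' @export
write_gaze_table <- function(gaze, path) {
  readr::write_tsv(gaze, path, na = "")
  invisible(path)
}

#' @rdname write_gaze_table
#' @export
read_gaze_table <- function(path, geometry = screen_geometry(),
                            col_map = NULL) {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  gz <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      names(gz)[names(gz) == col_map[[canon]]] <- canon
    }
  }
  required <- c("participant_id", "trial_id", "t_ms", "lx", "ly", "rx",
                "ry", "l_valid", "r_valid")
  missing <- setdiff(required, names(gz))
  if (length(missing) > 0) {
    stop("gaze table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  split_key <- paste(gz$participant_id, gz$trial_id)
  for (k in unique(split_key)) {
    tt <- gz$t_ms[split_key == k]
    if (any(diff(tt) <= 0)) {
      stop("non-monotone timestamps in participant/trial ", k)
    }
  }
  out_l <- gz$l_valid == 1 &
    (is.na(gz$lx) | gz$lx < 0 | gz$lx > geometry$width_px |
       is.na(gz$ly) | gz$ly < 0 | gz$ly > geometry$height_px)
  out_r <- gz$r_valid == 1 &
    (is.na(gz$rx) | gz$rx < 0 | gz$rx > geometry$width_px |
       is.na(gz$ry) | gz$ry < 0 | gz$ry > geometry$height_px)
  gz$l_valid[out_l] <- 0L
  gz$r_valid[out_r] <- 0L
  gz
}

#' Write and read analysis tables
#'
#' All stage outputs (trial designs, scores, tensors, clusters, growth
#' coefficients, divergence estimates, correlations, indices, curves) are
#' written as CSV with a schema-version comment line
#' (`# vwpred <name> v1`) as the first row. Numeric values round-trip at
#' full double precision.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @param name Schema name recorded in the header.
#' @return `read_result()` returns the tibble; writers return `path`
#'   invisibly.
#' @export
write_result <- function(x, path, name = "table") {
  writeLines(paste0("# vwpred ", name, " v1"), path)
  readr::write_csv(x, path, na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a bundle of stage results
#'
#' Writes one CSV per result class into `out_dir`: whichever of
#' `clusters`, `growth`, `order_table`, `divergence`, `difference`,
#' `correlations`, `indices`, `curves`, `scores`, `designs`, `tensor`,
#' `accuracy` are present in `results`. Empty tibbles produce header-only
#' files.
#'
#' @param results Named list of tibbles.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir)
  }
  files <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.null(x)) next
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write_result(tibble::as_tibble(x), path, name = nm)
    files[[nm]] <- path
  }
  files
}
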