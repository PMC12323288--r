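#' Screen and viewing geometry
#'
#' Bundles the physical display parameters needed to convert between pixels
#' and degrees of visual angle: screen resolution, physical diagonal, viewing
#' distance and the tracker sampling rate. Defaults describe a 24-inch
#' 1920x1080 display viewed at 650 mm, sampled at 120 Hz.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_mm Physical diagonal of the display in millimetres
#'   (24 inch = 609.6 mm).
#' @param distance_mm Viewing distance in millimetres.
#' @param hz Sampling rate of the eye tracker in Hz.
#' @return An object of class `vwp_geometry`: a list with the inputs plus
#'   `pitch_mm` (physical size of one pixel) and `sample_period_ms`.
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            diagonal_mm = 609.6, distance_mm = 650,
                            hz = 120) {
  stopifnot(width_px > 0, height_px > 0, diagonal_mm > 0, distance_mm > 0,
            hz > 0)
  pitch <- diagonal_mm / sqrt(width_px^2 + height_px^2)
  structure(
    list(width_px = width_px, height_px = height_px,
         diagonal_mm = diagonal_mm, distance_mm = distance_mm, hz = hz,
         pitch_mm = pitch, sample_period_ms = 1000 / hz),
    class = "vwp_geometry"
  )
}

#' Convert between pixels and degrees of visual angle
#'
#' Uses a flat-screen model: a span of `px` pixels at the screen centre
#' subtends `atan(px * pitch / distance)` radians. At the default geometry
#' one degree is about 41 px.
#'
#' @param px,deg Quantity to convert.
#' @param geometry A [screen_geometry()] object.
#' @return Converted value (vectorised).
#' @export
px_to_deg <- function(px, geometry) {
  atan2(px * geometry$pitch_mm, geometry$distance_mm) * 180 / pi
}

#' @rdname px_to_deg
#' @export
deg_to_px <- function(deg, geometry) {
  tan(deg * pi / 180) * geometry$distance_mm / geometry$pitch_mm
}

#' Four-quadrant AOI layout
#'
#' Places four equally sized square areas of interest (AOIs), one per screen
#' quadrant, equidistant from the screen centre. Each region is half-open:
#' a point belongs to it if `left <= x < left + size` and
#' `top <= y < top + size`.
#'
#' @param size_px Side of each square AOI in pixels.
#' @param offset_x,offset_y Horizontal/vertical distance from screen centre
#'   to each AOI centre, in pixels.
#' @param geometry A [screen_geometry()] object.
#' @return A `vwp_aoi_layout`: tibble with one row per screen position
#'   (`pos1`..`pos4`, reading order top-left, top-right, bottom-left,
#'   bottom-right) and columns `position`, `left`, `top`, `size`.
#' @export
aoi_layout <- function(size_px = 384, offset_x = 420, offset_y = 270,
                       geometry = screen_geometry()) {
  cx <- geometry$width_px / 2
  cy <- geometry$height_px / 2
  half <- size_px / 2
  centers_x <- cx + c(-1, 1, -1, 1) * offset_x
  centers_y <- cy + c(-1, -1, 1, 1) * offset_y
  layout <- tibble::tibble(
    position = paste0("pos", 1:4),
    left = centers_x - half,
    top = centers_y - half,
    size = size_px
  )
  if (offset_x < half || offset_y < half) {
    stop("AOI regions overlap: offsets must be at least half the AOI size")
  }
  if (any(layout$left < 0) || any(layout$top < 0) ||
      any(layout$left + size_px > geometry$width_px) ||
      any(layout$top + size_px > geometry$height_px)) {
    stop("AOI regions extend beyond the screen")
  }
  structure(layout, class = c("vwp_aoi_layout", class(layout)))
}

#' Sentence timing landmarks
#'
#' Millisecond offsets (from sentence onset) of the spoken-sentence
#' components and of the analysis window end: verb onset 750 ms, patient
#' onset 1300 ms, sentence offset 2100 ms, analysis window end 2500 ms.
#'
#' @return Named numeric vector.
#' @export
timing_landmarks <- function() {
  c(agent_onset = 0, verb_onset = 750, patient_onset = 1300,
    sentence_offset = 2100, window_end = 2500)
}
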