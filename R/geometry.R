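#' Display geometry
#'
#' Pixel and visual-angle description of the stimulus display. The study
#' display showed 918 x 672 px images subtending 32.4 x 23.7 degrees of
#' visual angle; those are the defaults. The pixels-per-degree scale is
#' derived from the width and must agree with the height-derived value
#' within 0.5%.
#'
#' @param width_px,height_px image size in pixels.
#' @param width_deg,height_deg image size in degrees of visual angle.
#' @param background_level gray background pixel level (default 127).
#' @param luminance optional named list of luminance metadata in cd/m^2
#'   (recorded only; the package performs no photometric calibration).
#' @return Object of class `display_geometry` with derived `px_per_deg`.
#' @export
display_geometry <- function(width_px = 918L, height_px = 672L,
                             width_deg = 32.4, height_deg = 23.7,
                             background_level = 127L,
                             luminance = list(white = 35, black = 1, gray = 12)) {
  assert_scalar_number(width_px, "width_px", 1, Inf)
  assert_scalar_number(height_px, "height_px", 1, Inf)
  assert_scalar_number(width_deg, "width_deg", 1e-6, Inf)
  assert_scalar_number(height_deg, "height_deg", 1e-6, Inf)
  ppd_w <- width_px / width_deg
  ppd_h <- height_px / height_deg
  if (abs(ppd_w - ppd_h) / ppd_w > 0.005) {
    stop(sprintf("inconsistent pixel pitch: %.3f px/deg from width vs %.3f from height",
                 ppd_w, ppd_h), call. = FALSE)
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         width_deg = width_deg, height_deg = height_deg,
         px_per_deg = ppd_w, background_level = as.integer(background_level),
         luminance = luminance),
    class = "display_geometry"
  )
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("Display geometry: %d x %d px, %.1f x %.1f deg (%.2f px/deg), background %d\n",
              x$width_px, x$height_px, x$width_deg, x$height_deg,
              x$px_per_deg, x$background_level))
  invisible(x)
}

#' Square-annulus eccentricity frame
#'
#' The region between two concentric axis-aligned squares centered on the
#' image center, delimited by the inner and outer eccentricities (Chebyshev
#' distance in degrees). Fragments are constrained to lie entirely inside
#' this band.
#'
#' @param inner_deg,outer_deg inner and outer eccentricity bounds in
#'   degrees (study values 4.8 and 8.8).
#' @return Object of class `frame_region`.
#' @export
frame_region <- function(inner_deg = 4.8, outer_deg = 8.8) {
  assert_scalar_number(inner_deg, "inner_deg", 0, Inf)
  assert_scalar_number(outer_deg, "outer_deg", 0, Inf)
  if (inner_deg >= outer_deg) stop("`inner_deg` must be < `outer_deg`", call. = FALSE)
  structure(list(inner_deg = inner_deg, outer_deg = outer_deg),
            class = "frame_region")
}

#' @export
print.frame_region <- function(x, ...) {
  cat(sprintf("Square-annulus frame: %.1f-%.1f deg eccentricity\n",
              x$inner_deg, x$outer_deg))
  invisible(x)
}

#' Convert degrees of visual angle to pixels
#'
#' Nearest-integer conversion with ties rounded toward the smaller value,
#' so e.g. 0.3 deg maps to 8 px on the study geometry.
#'
#' @param deg size in degrees (vectorized).
#' @param geometry a [display_geometry].
#' @return Integer pixel sizes.
#' @export
deg_to_px <- function(deg, geometry) {
  stopifnot(inherits(geometry, "display_geometry"))
  as.integer(ceiling(deg * geometry$px_per_deg - 0.5))
}

#' Fraction of image area revealed by square fragments
#'
#' `count * size_deg^2 / (width_deg * height_deg)`: the nominal visible
#' area fraction quoted with each stimulus condition (e.g. ten 2.4-deg
#' fragments reveal 7.5% of the study image).
#'
#' @param size_deg fragment side in degrees.
#' @param count number of fragments.
#' @param geometry a [display_geometry].
#' @return Fraction in \[0, 1\].
#' @export
visible_area_fraction <- function(size_deg, count, geometry) {
  stopifnot(inherits(geometry, "display_geometry"))
  assert_scalar_number(size_deg, "size_deg", 1e-9, Inf)
  assert_scalar_number(count, "count", 0, Inf)
  count * size_deg^2 / (geometry$width_deg * geometry$height_deg)
}

#' Visual angle subtended by one pattern tile
#'
#' @param geometry a [display_geometry].
#' @param pattern_size tile side in pixels (default 3).
#' @return Side length in degrees (about 0.1 deg on the study geometry).
#' @export
feature_subtense_deg <- function(geometry, pattern_size = 3L) {
  stopifnot(inherits(geometry, "display_geometry"))
  pattern_size / geometry$px_per_deg
}

#' Area fraction of the eccentricity frame
#'
#' Area of the square annulus relative to the full image, computed in
#' degrees: `4 * (outer^2 - inner^2) / (width_deg * height_deg)`.
#'
#' @param frame a [frame_region].
#' @param geometry a [display_geometry].
#' @return Fraction of image area.
#' @export
frame_area_fraction <- function(frame, geometry) {
  stopifnot(inherits(frame, "frame_region"), inherits(geometry, "display_geometry"))
  4 * (frame$outer_deg^2 - frame$inner_deg^2) /
    (geometry$width_deg * geometry$height_deg)
}
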