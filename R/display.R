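#' Physical display specification
#'
#' Describes the monitor geometry and viewing distance that fix the
#' pixel-to-degree conversion, together with the display's contrast limits.
#' Defaults reproduce a 1024 x 768 CRT of width 38.25 cm viewed from 130 cm
#' with a background of 85 cd/m^2 and a maximum displayable negative contrast
#' of -0.87.
#'
#' @param width_cm physical width of the display, cm.
#' @param width_px horizontal resolution, pixels.
#' @param height_px vertical resolution, pixels.
#' @param viewing_distance_cm eye-to-screen distance, cm.
#' @param refresh_hz refresh rate, Hz.
#' @param background_luminance_cdm2 background luminance, cd/m^2.
#' @param max_neg_contrast most negative displayable Weber contrast
#'   (must lie in \[-1, 0\]).
#' @return An object of class `display_spec`.
#' @export
#' @examples
#' d <- display_spec()
#' pixels_to_degrees(45, d)
display_spec <- function(width_cm = 38.25, width_px = 1024, height_px = 768,
                         viewing_distance_cm = 130, refresh_hz = 85,
                         background_luminance_cdm2 = 85,
                         max_neg_contrast = -0.87) {
  num <- c(width_cm = width_cm, width_px = width_px, height_px = height_px,
           viewing_distance_cm = viewing_distance_cm, refresh_hz = refresh_hz,
           background_luminance_cdm2 = background_luminance_cdm2)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all physical display quantities must be finite and positive")
  if (!is.finite(max_neg_contrast) || max_neg_contrast > 0 ||
      abs(max_neg_contrast) > 1)
    stop("max_neg_contrast must lie in [-1, 0]")
  structure(list(width_cm = width_cm, width_px = width_px,
                 height_px = height_px,
                 viewing_distance_cm = viewing_distance_cm,
                 refresh_hz = refresh_hz,
                 background_luminance_cdm2 = background_luminance_cdm2,
                 max_neg_contrast = max_neg_contrast),
            class = "display_spec")
}

#' Default display used throughout the package
#' @return A `display_spec`.
#' @export
default_display <- function() display_spec()

#' Convert a pixel extent to degrees of visual angle
#'
#' Uses the small-angle form (arc length over viewing distance); at the
#' sizes involved here the exact arctangent form differs only in the fourth
#' decimal place.
#'
#' @param px extent in pixels (non-negative).
#' @param display a [display_spec()].
#' @return Visual angle in degrees.
#' @export
pixels_to_degrees <- function(px, display = default_display()) {
  stopifnot(inherits(display, "display_spec"))
  if (any(px < 0)) stop("px must be non-negative")
  cm_per_px <- display$width_cm / display$width_px
  (px * cm_per_px / display$viewing_distance_cm) * 180 / pi
}

#' Area of one pixel in squared degrees
#'
#' @param display a [display_spec()].
#' @return Pixel area in deg^2; about 2.71e-4 deg^2 for the default display.
#' @export
pixel_area_deg2 <- function(display = default_display()) {
  pixels_to_degrees(1, display)^2
}
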