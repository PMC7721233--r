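#' Display geometry of the projection screen
#'
#' Describes the physical screen used to present the dot stimuli: a
#' back-projected panel viewed through a mirror at a short distance, so each
#' pixel subtends a visual angle that depends on the participant's viewing
#' distance.
#'
#' @param screen_width_cm,screen_height_cm Usable screen size in centimetres.
#' @param resolution_x,resolution_y Screen resolution in pixels.
#' @param refresh_hz Display refresh rate in Hz.
#' @param viewing_distance_cm Eye-to-screen distance in centimetres.
#'
#' @return An object of class `display_geometry`.
#' @examples
#' geom <- display_geometry(viewing_distance_cm = 25)
#' pixel_visual_angle(geom)
#' @export
display_geometry <- function(screen_width_cm = 12,
                             screen_height_cm = 9,
                             resolution_x = 1024,
                             resolution_y = 768,
                             refresh_hz = 60,
                             viewing_distance_cm = 25) {
  assert_scalar_number(screen_width_cm, "screen_width_cm", 0, strict = TRUE)
  assert_scalar_number(screen_height_cm, "screen_height_cm", 0, strict = TRUE)
  assert_scalar_number(resolution_x, "resolution_x", 0, strict = TRUE)
  assert_scalar_number(resolution_y, "resolution_y", 0, strict = TRUE)
  assert_scalar_number(refresh_hz, "refresh_hz", 0, strict = TRUE)
  assert_scalar_number(viewing_distance_cm, "viewing_distance_cm", 0, strict = TRUE)
  if (viewing_distance_cm < 1 || viewing_distance_cm > 500) {
    abort("`viewing_distance_cm` must lie between 1 and 500 cm.")
  }
  structure(
    list(
      screen_width_cm = screen_width_cm,
      screen_height_cm = screen_height_cm,
      resolution_x = resolution_x,
      resolution_y = resolution_y,
      refresh_hz = refresh_hz,
      viewing_distance_cm = viewing_distance_cm
    ),
    class = "display_geometry"
  )
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf(
    "<display_geometry> %g x %g cm, %d x %d px, %g Hz, viewed at %g cm (%.4f deg/px)\n",
    x$screen_width_cm, x$screen_height_cm, x$resolution_x, x$resolution_y,
    x$refresh_hz, x$viewing_distance_cm, pixel_visual_angle(x)
  ))
  invisible(x)
}

#' Visual angle subtended by one pixel
#'
#' Converts the physical width of one pixel to degrees of visual angle by the
#' small-angle approximation `angle = width / distance` (radians), which is
#' accurate to well below printing precision at the sub-millimetre pixel sizes
#' and >20 cm viewing distances involved.
#'
#' @param geometry A [display_geometry()].
#' @return Degrees of visual angle per pixel (scalar).
#' @export
pixel_visual_angle <- function(geometry) {
  stopifnot(inherits(geometry, "display_geometry"))
  px_cm <- geometry$screen_width_cm / geometry$resolution_x
  (px_cm / geometry$viewing_distance_cm) * 180 / pi
}

#' Dot speed in degrees of visual angle per second
#'
#' @param px_per_frame Displacement per video frame, in pixels.
#' @param geometry A [display_geometry()]; supplies the refresh rate and the
#'   per-pixel angle.
#' @param deg_per_px Optional per-pixel visual angle override (degrees). By
#'   default it is computed from `geometry`; pass a rounded published value to
#'   reproduce speeds quoted at that printing precision.
#' @return Speed in degrees per second.
#' @export
speed_deg_per_s <- function(px_per_frame, geometry, deg_per_px = NULL) {
  assert_scalar_number(px_per_frame, "px_per_frame", 0)
  stopifnot(inherits(geometry, "display_geometry"))
  if (is.null(deg_per_px)) deg_per_px <- pixel_visual_angle(geometry)
  px_per_frame * geometry$refresh_hz * deg_per_px
}

#' Stimulus configuration for the paired-dot Glass patterns
#'
#' Parameters of the dot texture shared by all three conditions: 250 white dot
#' pairs on a dark background, a maximum within-pair separation of 8 pixels
#' along the Glass axis, and a 150 ms limited dot lifetime.
#'
#' @param n_pairs Number of dot pairs.
#' @param dot_size_px Dot side length in pixels (square dots).
#' @param max_pair_sep_px Maximum within-pair separation in pixels; also the
#'   distance each moving dot travels over one lifetime.
#' @param dot_lifetime_s Limited dot lifetime in seconds; must be an integer
#'   number of frames at the display refresh rate.
#' @param dot_luminance,background_luminance Luminances in cd/m^2 (metadata
#'   only; not used in computation).
#' @param fixation_size_px Fixation square side in pixels (metadata only).
#' @return An object of class `glass_config`.
#' @export
glass_config <- function(n_pairs = 250,
                         dot_size_px = 3,
                         max_pair_sep_px = 8,
                         dot_lifetime_s = 0.150,
                         dot_luminance = 67,
                         background_luminance = 4,
                         fixation_size_px = 5) {
  assert_scalar_number(n_pairs, "n_pairs", 1)
  assert_scalar_number(max_pair_sep_px, "max_pair_sep_px", 0, strict = TRUE)
  assert_scalar_number(dot_lifetime_s, "dot_lifetime_s", 0, strict = TRUE)
  structure(
    list(
      n_pairs = as.integer(n_pairs),
      dot_size_px = dot_size_px,
      max_pair_sep_px = max_pair_sep_px,
      dot_lifetime_s = dot_lifetime_s,
      dot_luminance = dot_luminance,
      background_luminance = background_luminance,
      fixation_size_px = fixation_size_px
    ),
    class = "glass_config"
  )
}

# Lifetime in frames; errors unless the lifetime is a whole number of frames.
lifetime_frames <- function(config, geometry) {
  lf <- config$dot_lifetime_s * geometry$refresh_hz
  if (abs(lf - round(lf)) > 1e-9 || round(lf) < 1) {
    abort(sprintf(
      "dot lifetime (%g s) is not a positive whole number of frames at %g Hz",
      config$dot_lifetime_s, geometry$refresh_hz
    ))
  }
  as.integer(round(lf))
}
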