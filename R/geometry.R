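#' Optical geometry of a point-source in-line holographic microscope
#'
#' Describes the recording geometry of a lensless in-line holographic
#' microscope: a point source (pinhole) at the origin illuminates a volume,
#' and the interference pattern is recorded on a pixelated sensor a distance
#' `distance` away along the optical axis (+z). All lengths are in
#' micrometres.
#'
#' Derived quantities are stored on the object: the effective wavelength in
#' the medium `wavelength / medium_index`, the wavenumber
#' `k = 2 * pi * medium_index / wavelength`, and the physical screen width and
#' height `ncol * pitch`, `nrow * pitch`.
#'
#' Pixel centres follow image convention: x to the right, y down, sensor
#' pixel `(r, c)` (0-based) centred at
#' `((c + 0.5) * pitch - W/2, (r + 0.5) * pitch - H/2, distance)`.
#'
#' @param wavelength Vacuum wavelength of the source, µm (default 0.405, a
#'   violet diode laser).
#' @param medium_index Refractive index of the propagation medium (>= 1);
#'   1 for air, 1.33 for water (where the effective wavelength drops to
#'   roughly 300 nm for a 405 nm source).
#' @param distance Source-to-screen distance d, µm (default 5000).
#' @param pixel_pitch Sensor pixel pitch p, µm (default 5.5).
#' @param sensor_shape Integer pair `(rows, cols)` (default `c(2048, 2048)`).
#' @return An object of class `optical_geometry`.
#' @examples
#' geom <- optical_geometry()
#' numerical_aperture(geom)
#' lateral_resolution(geom) * 1000 # nm
#' @export
optical_geometry <- function(wavelength = 0.405, medium_index = 1,
                             distance = 5000, pixel_pitch = 5.5,
                             sensor_shape = c(2048L, 2048L)) {
  stopifnot(
    is.numeric(wavelength), length(wavelength) == 1, wavelength > 0,
    is.numeric(medium_index), length(medium_index) == 1, medium_index >= 1,
    is.numeric(distance), length(distance) == 1, distance > 0,
    is.numeric(pixel_pitch), length(pixel_pitch) == 1, pixel_pitch > 0,
    length(sensor_shape) == 2, all(sensor_shape >= 2)
  )
  sensor_shape <- as.integer(sensor_shape)
  g <- list(
    wavelength = wavelength,
    medium_index = medium_index,
    distance = distance,
    pixel_pitch = pixel_pitch,
    sensor_shape = sensor_shape,
    effective_wavelength = wavelength / medium_index,
    wavenumber = 2 * pi * medium_index / wavelength,
    screen_width = sensor_shape[2] * pixel_pitch,
    screen_height = sensor_shape[1] * pixel_pitch
  )
  structure(g, class = "optical_geometry")
}

#' @export
print.optical_geometry <- function(x, ...) {
  cat("<optical_geometry>\n")
  cat(sprintf("  wavelength     : %g um (in medium: %g um, n_m = %g)\n",
              x$wavelength, x$effective_wavelength, x$medium_index))
  cat(sprintf("  source-screen  : %g um\n", x$distance))
  cat(sprintf("  sensor         : %d x %d px, pitch %g um (%g x %g um)\n",
              x$sensor_shape[1], x$sensor_shape[2], x$pixel_pitch,
              x$screen_width, x$screen_height))
  cat(sprintf("  NA             : %.4f  (lateral %.0f nm, depth %.0f nm)\n",
              numerical_aperture(x), 1000 * lateral_resolution(x),
              1000 * depth_resolution(x)))
  invisible(x)
}

is_geometry <- function(x) inherits(x, "optical_geometry")

# x, y, z coordinates (um) of every sensor pixel centre, image convention.
sensor_coordinates <- function(geometry) {
  nr <- geometry$sensor_shape[1]
  nc <- geometry$sensor_shape[2]
  p <- geometry$pixel_pitch
  list(
    x = (seq_len(nc) - 0.5) * p - geometry$screen_width / 2,
    y = (seq_len(nr) - 0.5) * p - geometry$screen_height / 2,
    z = geometry$distance
  )
}

#' Numerical aperture of the recording geometry
#'
#' The default (and physically meaningful) definition is the sine of the
#' half-angle subtended by the screen half-width at the source:
#' `NA = (W/2) / sqrt((W/2)^2 + d^2)`, which is always in (0, 1) and is the
#' value consistent with the diffraction-limited resolution formulas used by
#' [lateral_resolution()] and [depth_resolution()].
#'
#' An alternative ratio convention `W / (2 * sqrt((d/2)^2 + d^2))` is
#' exposed via `formula = "ratio"` for comparison; it is not a sine of any
#' angle and can exceed 1 for wide screens, so it is never used internally.
#'
#' @param geometry An [optical_geometry()].
#' @param formula `"half-angle"` (default) or `"ratio"`.
#' @return Dimensionless numerical aperture.
#' @export
numerical_aperture <- function(geometry, formula = c("half-angle", "ratio")) {
  stopifnot(is_geometry(geometry))
  formula <- match.arg(formula)
  w2 <- geometry$screen_width / 2
  d <- geometry$distance
  if (w2 <= 0 || d <= 0) stop("screen width and distance must be positive")
  switch(formula,
    "half-angle" = w2 / sqrt(w2^2 + d^2),
    "ratio" = geometry$screen_width / (2 * sqrt((d / 2)^2 + d^2))
  )
}

#' Diffraction-limited lateral resolution
#'
#' `lambda_eff / (2 NA)` with `lambda_eff` the wavelength in the medium.
#'
#' @inheritParams numerical_aperture
#' @return Length in µm.
#' @export
lateral_resolution <- function(geometry) {
  stopifnot(is_geometry(geometry))
  geometry$effective_wavelength / (2 * numerical_aperture(geometry))
}

#' Diffraction-limited depth (axial) resolution
#'
#' `lambda_eff / (2 NA^2)`. Depth resolution is always the coarser of the
#' two limits since NA <= 1.
#'
#' @inheritParams numerical_aperture
#' @return Length in µm.
#' @export
depth_resolution <- function(geometry) {
  stopifnot(is_geometry(geometry))
  geometry$effective_wavelength / (2 * numerical_aperture(geometry)^2)
}

#' Sensor field of view
#'
#' Physical area of the recording screen.
#'
#' @inheritParams numerical_aperture
#' @param units `"cm2"` (default) or `"um2"`.
#' @return Area in the requested units.
#' @export
field_of_view <- function(geometry, units = c("cm2", "um2")) {
  stopifnot(is_geometry(geometry))
  units <- match.arg(units)
  a <- geometry$screen_width * geometry$screen_height # um^2
  if (units == "cm2") a / 1e8 else a
}

#' Frame interval of a hologram video
#'
#' @param frame_rate Frames per second.
#' @return Interval between frames in seconds (62.5 ms at 16 fps).
#' @export
frame_interval <- function(frame_rate) {
  stopifnot(is.numeric(frame_rate), length(frame_rate) == 1, frame_rate > 0)
  1 / frame_rate
}

#' Resolution report for a recording geometry
#'
#' One-row tibble collecting the numerical aperture and the theoretical
#' lateral and depth resolution limits of the geometry, in nanometres.
#'
#' @inheritParams numerical_aperture
#' @return A tibble with columns `numerical_aperture`, `lateral_limit_nm`,
#'   `depth_limit_nm`, `wavelength_um`, `medium_index`, `field_of_view_cm2`.
#' @examples
#' resolution_report(optical_geometry())
#' @export
resolution_report <- function(geometry) {
  stopifnot(is_geometry(geometry))
  na <- numerical_aperture(geometry)
  tibble::tibble(
    numerical_aperture = na,
    lateral_limit_nm = 1000 * lateral_resolution(geometry),
    depth_limit_nm = 1000 * depth_resolution(geometry),
    wavelength_um = geometry$wavelength,
    medium_index = geometry$medium_index,
    field_of_view_cm2 = field_of_view(geometry)
  )
}
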