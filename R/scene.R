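#' Build a table of point scatterers
#'
#' A scatterer is a weak point-like object in the illuminated volume,
#' described by its 3D position (source at the origin, +z toward the
#' screen), a nominal diameter, a refractive index and a complex scattering
#' amplitude (first-Born strength; a free model parameter, dimensionless in
#' the package's µm length convention).
#'
#' @param x,y,z Position coordinates, µm. Vectors are recycled to a common
#'   length.
#' @param diameter Nominal particle diameter, µm.
#' @param refractive_index Particle refractive index `n_obj` (1.5983 is
#'   polystyrene at 405 nm).
#' @param amplitude Complex scattering amplitude. The default 150 gives
#'   fringe visibility of order 0.1 at the default geometry.
#' @return A tibble with columns `x_um`, `y_um`, `z_um`, `diameter_um`,
#'   `n_obj`, `amplitude`.
#' @examples
#' scatterers(x = 0, y = 0, z = 2000, diameter = 0.1)
#' @export
scatterers <- function(x = 0, y = 0, z, diameter = 0.1,
                       refractive_index = 1.5983, amplitude = 150) {
  tb <- tibble::tibble(
    x_um = as.numeric(x), y_um = as.numeric(y), z_um = as.numeric(z),
    diameter_um = as.numeric(diameter),
    n_obj = as.numeric(refractive_index),
    amplitude = as.complex(amplitude)
  )
  if (any(tb$diameter_um <= 0)) stop("diameter must be positive")
  tb
}

#' Assemble a scene for hologram simulation
#'
#' A scene is a (possibly empty) table of scatterers plus a frame time.
#' An empty scene is a background scene.
#'
#' @param scatterers A tibble as produced by [scatterers()], or `NULL` for
#'   an empty (background) scene.
#' @param frame_time Acquisition time of the frame, seconds.
#' @return A tibble of scatterers with attribute `frame_time`, class
#'   `holo_scene`.
#' @export
scene <- function(scatterers = NULL, frame_time = 0) {
  if (is.null(scatterers)) {
    scatterers <- tibble::tibble(
      x_um = numeric(), y_um = numeric(), z_um = numeric(),
      diameter_um = numeric(), n_obj = numeric(), amplitude = complex()
    )
  }
  req <- c("x_um", "y_um", "z_um", "diameter_um", "n_obj", "amplitude")
  if (!all(req %in% names(scatterers))) {
    stop("scatterers must have columns: ", paste(req, collapse = ", "))
  }
  out <- tibble::as_tibble(scatterers)
  attr(out, "frame_time") <- frame_time
  class(out) <- c("holo_scene", class(out))
  out
}

is_scene <- function(x) inherits(x, "holo_scene")

#' Scattering amplitude for a target fringe visibility
#'
#' The fringe contrast a point scatterer produces on the sensor scales as
#' `amplitude * d / (z * (d - z))` near the optical axis, so the amplitude
#' that yields a given visibility depends on where the particle sits. The
#' absolute scattering strength of the particles is a free model
#' parameter; fixing the fringe visibility instead is the natural way to
#' place simulations in a realistic detection regime.
#'
#' @param geometry An [optical_geometry()].
#' @param z Particle depth(s), µm.
#' @param visibility Target fringe visibility (default 0.25).
#' @return Amplitude value(s) for [scatterers()].
#' @export
scattering_amplitude <- function(geometry, z, visibility = 0.25) {
  stopifnot(is_geometry(geometry))
  d <- geometry$distance
  visibility * z * (d - z) / d
}

#' Discretize a sphere into a lattice of point scatterers
#'
#' Fills a sphere with point scatterers on a cubic lattice, for simulating
#' extended particles (e.g. for FWHM sizing studies). The per-point
#' amplitude is `amplitude / n_points`, so the summed scattering strength is
#' independent of the lattice spacing.
#'
#' @param center Length-3 numeric, sphere centre (x, y, z) in µm.
#' @param diameter Sphere diameter, µm.
#' @param spacing Lattice spacing, µm; must be at most `diameter / 2`.
#'   Defaults to a quarter of the effective wavelength at 405 nm in air.
#' @param refractive_index,amplitude Passed to [scatterers()]; `amplitude`
#'   is the *total* strength of the sphere.
#' @return A tibble of point scatterers (at least one row).
#' @examples
#' nrow(discretize_sphere(c(0, 0, 2000), diameter = 0.5, spacing = 0.1))
#' @export
discretize_sphere <- function(center, diameter, spacing = 0.405 / 4,
                              refractive_index = 1.5983, amplitude = 150) {
  stopifnot(length(center) == 3, is.numeric(center))
  if (!is.numeric(diameter) || diameter <= 0) stop("diameter must be positive")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be positive")
  if (spacing > diameter / 2) {
    # too coarse to resolve the volume: collapse to a single point
    return(scatterers(center[1], center[2], center[3], diameter,
                      refractive_index, amplitude))
  }
  r <- diameter / 2
  n1 <- floor(r / spacing)
  ax <- seq(-n1, n1) * spacing
  g <- expand.grid(dx = ax, dy = ax, dz = ax)
  keep <- g$dx^2 + g$dy^2 + g$dz^2 <= r^2
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) g <- data.frame(dx = 0, dy = 0, dz = 0)
  scatterers(
    x = center[1] + g$dx, y = center[2] + g$dy, z = center[3] + g$dz,
    diameter = spacing, refractive_index = refractive_index,
    amplitude = amplitude / nrow(g)
  )
}
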