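#' Construct a hologram object
#'
#' A hologram is a 2D grid of real intensities recorded (or simulated) on
#' the sensor described by `geometry`. Raw and background holograms are
#' nonnegative; contrast holograms (raw minus background) are signed.
#'
#' @param pixels Numeric matrix whose shape equals `geometry$sensor_shape`.
#' @param geometry An [optical_geometry()].
#' @param kind One of `"raw"`, `"background"`, `"contrast"`.
#' @param frame_index Integer frame number within a sequence.
#' @param frame_time Acquisition time, seconds.
#' @return An object of class `hologram`.
#' @export
hologram <- function(pixels, geometry, kind = c("raw", "background", "contrast"),
                     frame_index = 0L, frame_time = 0) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(pixels), is.numeric(pixels), is_geometry(geometry))
  if (!all(dim(pixels) == geometry$sensor_shape)) {
    stop("pixel grid shape must equal geometry$sensor_shape")
  }
  if (kind != "contrast" && any(pixels < 0)) {
    stop(kind, " hologram intensities must be nonnegative")
  }
  structure(
    list(pixels = pixels, geometry = geometry, kind = kind,
         frame_index = as.integer(frame_index), frame_time = frame_time),
    class = "hologram"
  )
}

is_hologram <- function(x) inherits(x, "hologram")

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram: %s, %d x %d px, frame %d (t = %g s)>\n",
              x$kind, nrow(x$pixels), ncol(x$pixels), x$frame_index,
              x$frame_time))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' Spherical reference wave at a screen point
#'
#' Amplitude of the unit-strength point-source reference wave at a point on
#' the sensor plane: `exp(i k R) / R` with `R` the distance from the source.
#'
#' @param geometry An [optical_geometry()].
#' @param screen_point Length-3 numeric (x, y, z) in µm; must not be the
#'   origin (the source is singular there).
#' @return Complex amplitude (units 1/µm for a unit source).
#' @examples
#' Mod(reference_wave(optical_geometry(), c(0, 0, 5000))) # 1/5000
#' @export
reference_wave <- function(geometry, screen_point) {
  stopifnot(is_geometry(geometry), length(screen_point) == 3)
  r <- sqrt(sum(screen_point^2))
  if (r == 0) stop("screen_point at the source (zero length): singular")
  exp(1i * geometry$wavenumber * r) / r
}

# Maximum local fringe spatial frequency (cycles/um) produced by each
# scatterer at the sensor corners: |sin(theta_scat) - sin(theta_ref)| / lambda_eff.
max_fringe_frequency <- function(sc, geometry) {
  d <- geometry$distance
  cx <- c(-1, 1, -1, 1) * geometry$screen_width / 2
  cy <- c(-1, -1, 1, 1) * geometry$screen_height / 2
  f <- 0
  for (j in seq_len(nrow(sc))) {
    rho <- sqrt((cx - sc$x_um[j])^2 + (cy - sc$y_um[j])^2)
    sin_s <- rho / sqrt(rho^2 + (d - sc$z_um[j])^2)
    rho0 <- sqrt(cx^2 + cy^2)
    sin_r <- rho0 / sqrt(rho0^2 + d^2)
    f <- max(f, abs(sin_s - sin_r) / geometry$effective_wavelength)
  }
  f
}

# Complex field (reference + scattered) on the sensor for a scene.
forward_field <- function(sc, geometry) {
  k <- geometry$wavenumber
  co <- sensor_coordinates(geometry)
  r_ref <- sqrt(outer(co$y^2, co$x^2, "+") + co$z^2)
  field <- exp(1i * k * r_ref) / r_ref
  for (j in seq_len(nrow(sc))) {
    rs <- sqrt(sc$x_um[j]^2 + sc$y_um[j]^2 + sc$z_um[j]^2)
    incident <- sc$amplitude[j] * exp(1i * k * rs) / rs
    dist <- sqrt(outer((co$y - sc$y_um[j])^2, (co$x - sc$x_um[j])^2, "+") +
                   (co$z - sc$z_um[j])^2)
    field <- field + incident * exp(1i * k * dist) / dist
  }
  field
}

#' Simulate a point-source in-line hologram
#'
#' Computes the interference of the spherical reference wave with the waves
#' scattered by each scene element (first-Born point-scatterer model: the
#' incident field at the scatterer, times its amplitude, re-propagated as a
#' spherical wave to each pixel), takes the squared modulus, rescales the
#' noiseless reference level to `intensity_level` mean counts, and adds
#' clipped zero-mean Gaussian sensor noise.
#'
#' A sampling guard evaluates the finest interference fringe produced at
#' the sensor corners; if it exceeds the pixel Nyquist limit the hologram is
#' aliased at the periphery. `on_undersampled` controls whether this is a
#' warning (default; the reference instrument geometry itself is aliased at
#' the edges for most object depths), an error, or silent.
#'
#' @param scene A [scene()] (possibly empty).
#' @param geometry An [optical_geometry()].
#' @param noise_std Standard deviation of additive Gaussian noise, in the
#'   same arbitrary units as `intensity_level`; must be >= 0.
#' @param seed Integer seed for the noise; the simulation is deterministic
#'   for a fixed seed, and bitwise deterministic when `noise_std = 0`.
#' @param intensity_level Mean of the noiseless reference intensity after
#'   scaling (arbitrary camera units, default 100).
#' @param on_undersampled `"warn"`, `"error"`, or `"none"`.
#' @return A [hologram()] of kind `"raw"`.
#' @examples
#' g <- optical_geometry(sensor_shape = c(64, 64))
#' h <- simulate_hologram(scene(scatterers(z = 500)), g, noise_std = 0)
#' @export
simulate_hologram <- function(scene, geometry, noise_std = 0, seed = 1L,
                              intensity_level = 100,
                              on_undersampled = c("warn", "error", "none")) {
  on_undersampled <- match.arg(on_undersampled)
  stopifnot(is_scene(scene), is_geometry(geometry))
  if (noise_std < 0) stop("noise_std must be >= 0")
  sc <- scene
  d <- geometry$distance
  if (nrow(sc) > 0) {
    if (any(sc$z_um <= 0 | sc$z_um >= d)) {
      stop("all scatterers must satisfy 0 < z < source_screen_distance")
    }
    f_max <- max_fringe_frequency(sc, geometry)
    f_nyq <- 1 / (2 * geometry$pixel_pitch)
    if (f_max > f_nyq && on_undersampled != "none") {
      msg <- sprintf(
        "fringes undersampled at sensor periphery (%.3g > Nyquist %.3g cycles/um)",
        f_max, f_nyq)
      if (on_undersampled == "error") stop(msg) else warning(msg)
    } else if (f_max > 0.9 * f_nyq && on_undersampled == "warn") {
      warning(sprintf("fringe frequency within 10%% of Nyquist (%.3g of %.3g)",
                      f_max, f_nyq))
    }
  }
  field <- forward_field(sc, geometry)
  co <- sensor_coordinates(geometry)
  ref_i <- 1 / (outer(co$y^2, co$x^2, "+") + co$z^2) # |A_ref|^2
  scale <- intensity_level / mean(ref_i)
  img <- Mod(field)^2 * scale
  if (noise_std > 0) {
    img <- with_seed(seed, img + matrix(rnorm(length(img), 0, noise_std),
                                        nrow(img), ncol(img)))
    img[img < 0] <- 0
  }
  hologram(img, geometry, "raw", frame_time = attr(scene, "frame_time") %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a background (object-free) hologram
#'
#' Identical to [simulate_hologram()] with an empty scene: the pure
#' reference intensity plus sensor noise.
#'
#' @inheritParams simulate_hologram
#' @return A [hologram()] of kind `"background"`.
#' @export
simulate_background <- function(geometry, noise_std = 0, seed = 1L,
                                intensity_level = 100) {
  h <- simulate_hologram(scene(), geometry, noise_std = noise_std, seed = seed,
                         intensity_level = intensity_level)
  h$kind <- "background"
  h
}

#' Contrast hologram (raw minus background)
#'
#' Pixelwise subtraction of a background hologram from a raw hologram,
#' suppressing the source profile and static artefacts; the result is
#' signed.
#'
#' @param raw,background [hologram()] objects sharing geometry and shape.
#' @return A [hologram()] of kind `"contrast"`.
#' @export
contrast_hologram <- function(raw, background) {
  stopifnot(is_hologram(raw), is_hologram(background))
  if (!all(dim(raw$pixels) == dim(background$pixels))) {
    stop("raw and background holograms have different shapes")
  }
  if (!isTRUE(all.equal(raw$geometry[c("wavelength", "medium_index",
                                       "distance", "pixel_pitch")],
                        background$geometry[c("wavelength", "medium_index",
                                              "distance", "pixel_pitch")]))) {
    stop("raw and background holograms have different geometries")
  }
  hologram(raw$pixels - background$pixels, raw$geometry, "contrast",
           frame_index = raw$frame_index, frame_time = raw$frame_time)
}
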