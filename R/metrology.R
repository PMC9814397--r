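#' Crosscut profile through a reconstructed view
#'
#' Samples a straight line segment through a 2D view (intensity, amplitude
#' or phase grid) by bilinear interpolation, returning positions in
#' micrometres along the cut. This is the standard way particle diameters
#' are read off a reconstruction, via [fwhm()].
#'
#' @param view Real matrix (e.g. one entry of [field_views()]).
#' @param p0,p1 Segment endpoints as `(row, col)` pairs in pixel
#'   coordinates (1-based, fractional allowed); both must lie inside the
#'   grid.
#' @param object_pixel Physical size of one pixel of `view`, µm.
#' @param samples Number of sample points along the segment (>= 2).
#' @param view_kind Label stored with the profile: `"intensity"`,
#'   `"amplitude"` or `"phase"`.
#' @return A tibble with columns `position_um`, `value` and attribute
#'   `view_kind`; positions are strictly increasing from 0.
#' @export
crosscut <- function(view, p0, p1, object_pixel = 1, samples = 256,
                     view_kind = c("intensity", "amplitude", "phase")) {
  view_kind <- match.arg(view_kind)
  stopifnot(is.matrix(view), length(p0) == 2, length(p1) == 2, samples >= 2)
  inside <- function(p) {
    p[1] >= 1 && p[1] <= nrow(view) && p[2] >= 1 && p[2] <= ncol(view)
  }
  if (!inside(p0) || !inside(p1)) stop("crosscut endpoints out of bounds")
  t <- seq(0, 1, length.out = samples)
  rr <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  r0 <- pmin(floor(rr), nrow(view) - 1)
  c0 <- pmin(floor(cc), ncol(view) - 1)
  fr <- rr - r0
  fc <- cc - c0
  v <- view[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    view[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    view[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    view[cbind(r0 + 1, c0 + 1)] * fr * fc
  seg_len <- sqrt(sum((p1 - p0)^2)) * object_pixel
  out <- tibble::tibble(position_um = t * seg_len, value = v)
  attr(out, "view_kind") <- view_kind
  out
}

#' Full width at half maximum of a profile
#'
#' Finds the unique global maximum of the profile and the two half-height
#' crossings on either side by linear interpolation. With
#' `baseline = "min"` (default) the half height is measured above the
#' profile minimum, appropriate for reconstruction crosscuts whose
#' background is nonzero; `baseline = "zero"` measures above zero, for
#' model profiles.
#'
#' @param profile A tibble with columns `position_um`, `value` (as from
#'   [crosscut()]), or a two-column data frame.
#' @param baseline `"min"` or `"zero"`.
#' @return Width in the units of `position_um`.
#' @examples
#' p <- tibble::tibble(position_um = seq(0, 2, 0.01),
#'                     value = exp(-(seq(0, 2, 0.01) - 1)^2 / (2 * 0.1^2)))
#' fwhm(p, baseline = "zero") # ~2.3548 * 0.1
#' @export
fwhm <- function(profile, baseline = c("min", "zero")) {
  baseline <- match.arg(baseline)
  pos <- profile$position_um
  val <- profile$value
  stopifnot(length(pos) == length(val), length(pos) >= 3)
  base <- if (baseline == "min") min(val) else 0
  imax <- which.max(val)
  half <- base + (val[imax] - base) / 2
  if (val[imax] <= base) stop("profile has no peak above baseline")
  cross <- function(idx) {
    # linear interpolation of the half-height crossing between idx, idx+1
    pos[idx] + (half - val[idx]) / (val[idx + 1] - val[idx]) *
      (pos[idx + 1] - pos[idx])
  }
  left <- NULL
  for (i in seq(imax - 1, 1)) {
    if (imax == 1) break
    if (val[i] <= half && val[i + 1] > half) {
      left <- cross(i)
      break
    }
  }
  right <- NULL
  if (imax < length(val)) {
    for (i in seq(imax, length(val) - 1)) {
      if (val[i] > half && val[i + 1] <= half) {
        right <- cross(i)
        break
      }
    }
  }
  if (is.null(left) || is.null(right)) {
    stop("unbounded peak: no half-height crossing on one side")
  }
  right - left
}

#' Relative phase shift across an object
#'
#' Phase accumulated by light of wavelength `wavelength` traversing a
#' thickness `thickness` of material with index `n_obj` embedded in a
#' medium of index `n_m`:
#' `delta_psi = (n_obj - n_m) * 2 * pi * thickness / wavelength` (signed,
#' not wrapped).
#'
#' @param n_obj,n_m Refractive indices of object and medium.
#' @param thickness Path length in the object, µm (>= 0).
#' @param wavelength Vacuum wavelength, µm (> 0).
#' @return Phase shift in radians.
#' @examples
#' phase_shift(1.4729, 1.518, thickness = 1, wavelength = 0.405) # glycerin in oil
#' @export
phase_shift <- function(n_obj, n_m, thickness, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  if (any(thickness < 0)) stop("thickness must be nonnegative")
  (n_obj - n_m) * 2 * pi * thickness / wavelength
}

#' Optical path difference from a phase shift
#'
#' `OP = wavelength * delta_psi / (2 * pi) = (n_obj - n_m) * thickness`.
#'
#' @param delta_psi Phase shift, radians.
#' @param wavelength Vacuum wavelength, µm.
#' @return Optical path difference, µm.
#' @export
optical_path <- function(delta_psi, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  wavelength * delta_psi / (2 * pi)
}

#' Refractive-index contrast from a measured phase shift
#'
#' Inverts [phase_shift()] for the index difference, given the object
#' thickness along the propagation direction:
#' `delta_n = wavelength * delta_psi / (2 * pi * thickness)`.
#'
#' @inheritParams optical_path
#' @param thickness Object thickness, µm (> 0).
#' @return Dimensionless index difference `n_obj - n_m`.
#' @export
refractive_index_difference <- function(delta_psi, thickness, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  if (any(thickness <= 0)) stop("thickness must be positive")
  wavelength * delta_psi / (2 * pi * thickness)
}

#' Object thickness from a measured phase shift
#'
#' Inverts [phase_shift()] for the thickness along the propagation
#' direction, given the two refractive indices:
#' `t = wavelength * delta_psi / (2 * pi * (n_obj - n_m))`.
#'
#' @inheritParams optical_path
#' @param n_obj,n_m Refractive indices; must differ.
#' @return Thickness, µm.
#' @export
thickness_from_phase <- function(delta_psi, n_obj, n_m, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  if (any(n_obj == n_m)) stop("indeterminate thickness: n_obj equals n_m")
  wavelength * delta_psi / (2 * pi * (n_obj - n_m))
}

#' Unwrap a 1D phase profile
#'
#' Removes 2*pi jumps from a wrapped phase crosscut so it can be used with
#' [optical_path()] and friends.
#'
#' @param phase Numeric vector of wrapped phases, radians.
#' @return Unwrapped phase vector (same length).
#' @export
unwrap_phase <- function(phase) {
  if (length(phase) < 2) return(phase)
  d <- diff(phase)
  d <- d - 2 * pi * round(d / (2 * pi))
  phase[1] + c(0, cumsum(d))
}
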