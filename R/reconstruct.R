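#' Reconstructed complex field at a refocus depth
#'
#' Result of applying the Kirchhoff-Helmholtz transform to a hologram:
#' a complex-valued grid sampled on the object plane at depth `z` from the
#' source, with effective object-plane pixel size
#' `object_pixel = pixel_pitch * z / distance` (cone-beam magnification
#' `d / z`).
#'
#' @param values Complex matrix of reconstructed amplitudes.
#' @param z Reconstruction depth, µm.
#' @param geometry The recording [optical_geometry()].
#' @return An object of class `reconstructed_field`.
#' @export
reconstructed_field <- function(values, z, geometry) {
  stopifnot(is.matrix(values), is.complex(values), is_geometry(geometry))
  structure(
    list(values = values, z = z, geometry = geometry,
         object_pixel = geometry$pixel_pitch * z / geometry$distance),
    class = "reconstructed_field"
  )
}

is_field <- function(x) inherits(x, "reconstructed_field")

#' @export
print.reconstructed_field <- function(x, ...) {
  cat(sprintf(
    "<reconstructed_field: %d x %d px at z = %g um (object pixel %.4g um)>\n",
    nrow(x$values), ncol(x$values), x$z, x$object_pixel))
  invisible(x)
}

#' Intensity, amplitude and phase views of a reconstructed field
#'
#' @param field A [reconstructed_field()].
#' @return Named list of real matrices: `intensity` (`|K|^2`), `amplitude`
#'   (`|K|`), and `phase` (`arg(K)` in `(-pi, pi]`, 0 where `K = 0`).
#' @export
field_views <- function(field) {
  stopifnot(is_field(field))
  amp <- Mod(field$values)
  ph <- Arg(field$values)
  ph[ph <= -pi] <- pi
  ph[amp == 0] <- 0
  list(intensity = amp^2, amplitude = amp, phase = ph)
}

check_recon_input <- function(contrast, z) {
  stopifnot(is_hologram(contrast))
  if (contrast$kind != "contrast") {
    warning("reconstructing a ", contrast$kind,
            " hologram; the undiffracted source term will dominate")
  }
  d <- contrast$geometry$distance
  if (any(z <= 0 | z >= d)) {
    stop("reconstruction depth z must lie strictly inside (0, ", d, ")")
  }
  invisible(TRUE)
}

# Object-plane pixel-centre coordinates at depth z (um), image convention.
object_coordinates <- function(geometry, z) {
  dx <- geometry$pixel_pitch * z / geometry$distance
  nr <- geometry$sensor_shape[1]
  nc <- geometry$sensor_shape[2]
  list(
    x = ((seq_len(nc) - 0.5) - nc / 2) * dx,
    y = ((seq_len(nr) - 0.5) - nr / 2) * dx,
    dx = dx
  )
}

# Kernel-space refocus coordinates for physical source-object distance z.
#
# The Kirchhoff-Helmholtz kernel exp(i k (xi . r) / |xi|) brings the image
# of a scatterer at physical distance z from the point source to focus at
# the kernel coordinate zeta = d z / (d - z) (stationary phase of the
# hologram fringe term against the kernel; zeta -> z in the usual DIHM
# regime z << d). Refocusing at physical depth z therefore evaluates the
# kernel at r = (x', y', zeta) with the lateral grid at pitch
# p * zeta / d; the grid *index* then corresponds to the object-plane
# position at pitch p * z / d, which is what the returned field reports.
kernel_coordinates <- function(geometry, z) {
  d <- geometry$distance
  zeta <- d * z / (d - z)
  dxk <- geometry$pixel_pitch * zeta / d
  nr <- geometry$sensor_shape[1]
  nc <- geometry$sensor_shape[2]
  list(
    x = ((seq_len(nc) - 0.5) - nc / 2) * dxk,
    y = ((seq_len(nr) - 0.5) - nr / 2) * dxk,
    zeta = zeta,
    dxk = dxk
  )
}

#' Kirchhoff-Helmholtz reconstruction by direct summation
#'
#' Evaluates the Kirchhoff-Helmholtz transform
#' `K(r) = sum_xi I(xi) exp(i k (xi . r) / |xi|) dA` over every sensor
#' point `xi = (X, Y, d)`, with `r` on the object plane at depth `z`,
#' sampled at the object pixel pitch. This is the O(N^4) reference
#' implementation, exact up to floating point; it serves as the oracle for
#' [kh_reconstruct_fast()] and is only practical for small grids.
#'
#' @param contrast A contrast [hologram()] (a raw hologram is accepted with
#'   a warning).
#' @param z Reconstruction depth in (0, d), µm.
#' @return A [reconstructed_field()].
#' @export
kh_reconstruct_direct <- function(contrast, z) {
  check_recon_input(contrast, z)
  g <- contrast$geometry
  k <- g$wavenumber
  d <- g$distance
  co <- sensor_coordinates(g)
  kc <- kernel_coordinates(g, z)
  dA <- g$pixel_pitch^2
  I <- contrast$pixels
  K <- matrix(0i, nrow(I), ncol(I))
  for (pr in seq_len(nrow(I))) {
    for (pc in seq_len(ncol(I))) {
      v <- I[pr, pc]
      if (v == 0) next
      R <- sqrt(co$x[pc]^2 + co$y[pr]^2 + d^2)
      w <- v * dA * exp(1i * k * d * kc$zeta / R)
      K <- K + w * (exp(1i * k * co$y[pr] / R * kc$y) %o%
                      exp(1i * k * co$x[pc] / R * kc$x))
    }
  }
  reconstructed_field(K, z, g)
}

# Memoised gridding-correction factors phi_hat(2 pi m / ng) for the
# exponential-of-semicircle kernel, computed by Simpson quadrature.
es_correction_cache <- new.env(parent = emptyenv())

es_correction <- function(n_out, ng, width, beta) {
  key <- paste(n_out, ng, width, beta, sep = "_")
  hit <- es_correction_cache[[key]]
  if (!is.null(hit)) return(hit)
  cc <- width / 2
  np <- 4001 # odd, Simpson
  t <- seq(-cc, cc, length.out = np)
  h <- t[2] - t[1]
  phi <- exp(beta * (sqrt(pmax(0, 1 - (t / cc)^2)) - 1))
  sw <- rep(c(2, 4), length.out = np)
  sw[1] <- 1
  sw[np] <- 1
  m <- seq_len(n_out) - 1 - floor(n_out / 2)
  xi <- 2 * pi * m / ng
  corr <- as.vector(cos(outer(xi, t)) %*% (phi * sw)) * h / 3
  es_correction_cache[[key]] <- corr
  corr
}

# Type-1 NUFFT: K[r, c] = sum_j w_j exp(i (ky_j * mr + kx_j * mc)),
# mr = r - 1 - floor(nr/2), mc = c - 1 - floor(nc/2) (integers).
nufft_type1 <- function(ky, kx, w, nr, nc, width = 12L, oversample = 2L) {
  beta <- 2.3 * width
  ngr <- oversample * nr
  ngc <- oversample * nc
  gx <- (kx %% (2 * pi)) * ngc / (2 * pi)
  gy <- (ky %% (2 * pi)) * ngr / (2 * pi)
  G <- es_spread2(gy, gx, w, ngr, ngc, as.integer(width), beta)
  S <- stats::fft(G, inverse = TRUE)
  ir <- ((seq_len(nr) - 1 - floor(nr / 2)) %% ngr) + 1
  ic <- ((seq_len(nc) - 1 - floor(nc / 2)) %% ngc) + 1
  K <- S[ir, ic, drop = FALSE]
  K / (es_correction(nr, ngr, width, beta) %o%
         es_correction(nc, ngc, width, beta))
}

#' Fast Kirchhoff-Helmholtz reconstruction
#'
#' Evaluates the same transform as [kh_reconstruct_direct()] through a
#' type-1 non-uniform FFT: each sensor pixel contributes a plane-wave
#' component at frequency `k (X, Y) / |xi|`, which is gridded onto an
#' oversampled lattice with an exponential-of-semicircle kernel, FFT'd, and
#' deconvolved by the kernel transform. Frequencies are reduced mod 2*pi,
#' which is exact on the integer output grid, so the result agrees with the
#' direct sum to near machine precision while scaling as O(N^2 log N).
#'
#' @inheritParams kh_reconstruct_direct
#' @return A [reconstructed_field()].
#' @examples
#' g <- optical_geometry(sensor_shape = c(32, 32))
#' h <- simulate_hologram(scene(scatterers(z = 400)), g, noise_std = 0)
#' b <- simulate_background(g)
#' f <- kh_reconstruct_fast(contrast_hologram(h, b), z = 400)
#' @export
kh_reconstruct_fast <- function(contrast, z) {
  check_recon_input(contrast, z)
  g <- contrast$geometry
  k <- g$wavenumber
  d <- g$distance
  co <- sensor_coordinates(g)
  kc <- kernel_coordinates(g, z)
  dA <- g$pixel_pitch^2
  nr <- nrow(contrast$pixels)
  nc <- ncol(contrast$pixels)

  Rm <- sqrt(outer(co$y^2, co$x^2, "+") + d^2)
  kx <- (k * kc$dxk) * outer(rep(1, nr), co$x) / Rm
  ky <- (k * kc$dxk) * outer(co$y, rep(1, nc)) / Rm
  # half-pixel centring of the output grid, folded in before frequency wrap
  off_r <- 0.5 - nr / 2 + floor(nr / 2)
  off_c <- 0.5 - nc / 2 + floor(nc / 2)
  w <- contrast$pixels * dA *
    exp(1i * (k * d * kc$zeta / Rm + off_c * kx + off_r * ky))

  nz <- which(contrast$pixels != 0)
  if (length(nz) == 0) {
    return(reconstructed_field(matrix(0i, nr, nc), z, g))
  }
  K <- nufft_type1(ky[nz], kx[nz], w[nz], nr, nc)
  reconstructed_field(K, z, g)
}

#' Reconstruct a hologram at a series of depths
#'
#' @inheritParams kh_reconstruct_direct
#' @param z_values Strictly increasing reconstruction depths, µm.
#' @param method `"fast"` (default) or `"direct"`.
#' @return A `reconstruction_stack`: a list of [reconstructed_field()]s in
#'   depth order.
#' @export
reconstruct_volume <- function(contrast, z_values, method = c("fast", "direct")) {
  method <- match.arg(method)
  if (length(z_values) > 1 && any(diff(z_values) <= 0)) {
    stop("z_values must be strictly increasing")
  }
  fn <- if (method == "fast") kh_reconstruct_fast else kh_reconstruct_direct
  fields <- lapply(z_values, function(z) fn(contrast, z))
  structure(fields, class = "reconstruction_stack", z = as.numeric(z_values))
}

is_stack <- function(x) inherits(x, "reconstruction_stack")

#' @export
print.reconstruction_stack <- function(x, ...) {
  z <- attr(x, "z")
  cat(sprintf("<reconstruction_stack: %d plane(s)%s>\n", length(x),
              if (length(z)) sprintf(", z = %g..%g um", min(z), max(z)) else ""))
  invisible(x)
}

#' Wiener deconvolution of a reconstruction stack
#'
#' Per-plane Wiener sharpening using the coherent point-spread function of
#' the geometry at each plane (the reconstruction, at that plane, of the
#' contrast hologram of an on-axis unit point scatterer). The PSF is
#' re-centred before filtering so the operation introduces no shift.
#' `mode = "none"` returns the stack unchanged.
#'
#' @param stack A `reconstruction_stack` from [reconstruct_volume()].
#' @param mode `"none"` or `"wiener"`.
#' @param nsr Noise-to-signal ratio regularising the Wiener filter.
#' @return A `reconstruction_stack` of the same shape.
#' @export
deconvolve <- function(stack, mode = c("none", "wiener"), nsr = 0.05) {
  if (!is_stack(stack)) stop("stack must be a reconstruction_stack")
  if (length(stack) == 0) stop("stack is empty")
  mode <- match.arg(mode)
  if (mode == "none") return(stack)
  out <- lapply(stack, function(f) {
    psf <- plane_psf(f$geometry, f$z)
    H <- stats::fft(psf)
    H <- H / sqrt(mean(Mod(H)^2)) # unit-RMS transfer: near-unity passband gain
    Fv <- stats::fft(f$values)
    filt <- Conj(H) / (Mod(H)^2 + nsr)
    v <- stats::fft(Fv * filt, inverse = TRUE) / length(Fv)
    reconstructed_field(v, f$z, f$geometry)
  })
  structure(out, class = "reconstruction_stack", z = attr(stack, "z"))
}

# Coherent PSF of the geometry at depth z, peak-normalised and circularly
# shifted so the peak sits at element (1, 1) (zero-shift convention).
plane_psf <- function(geometry, z) {
  sc <- scene(scatterers(x = 0, y = 0, z = z, amplitude = 1))
  raw <- simulate_hologram(sc, geometry, noise_std = 0, on_undersampled = "none")
  bg <- simulate_background(geometry, noise_std = 0)
  f <- kh_reconstruct_fast(contrast_hologram(raw, bg), z)
  v <- f$values
  pk <- which.max(Mod(v))
  pr <- (pk - 1) %% nrow(v) + 1
  pc <- (pk - 1) %/% nrow(v) + 1
  v <- v[c(pr:nrow(v), seq_len(pr - 1)), c(pc:ncol(v), seq_len(pc - 1)),
         drop = FALSE]
  v / max(Mod(v))
}
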