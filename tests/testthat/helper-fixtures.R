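# Shared simulation geometries.
#
# `bench_geometry()` is the full instrument: 2048 x 2048 px at 5.5 µm,
# source-screen distance 5 mm, 405 nm — used for analytic metrology only.
#
# `crop_geometry()` is the same sensor pitch cropped to n x n pixels with
# the source at d/8 = 625 µm: it preserves the instrument's numerical
# aperture (0.7478) and therefore its 271 nm / 362 nm resolution limits,
# while a hologram of this size reconstructs in ~0.1 s. Scatterers are
# placed in the near-pinhole regime (z of tens of µm, magnification 30-80)
# where the fringes are Nyquist-sampled across the whole sensor.
#
# `wide_geometry()` is a low-NA variant (fine pitch, d = 5 mm) whose
# fringes stay Nyquist-clean for z across (0.2 d, 0.8 d).

bench_geometry <- function() optical_geometry()

crop_geometry <- function(n = 256) {
  optical_geometry(pixel_pitch = 5.5, distance = 625,
                   sensor_shape = c(n, n))
}

wide_geometry <- function(n = 128) {
  optical_geometry(pixel_pitch = 2.2, distance = 5000,
                   sensor_shape = c(n, n))
}

# One point scatterer at fringe visibility `vis`, simulated and
# background-subtracted.
point_contrast <- function(geometry, x = 0, y = 0, z, noise_std = 0,
                           seed = 1L, vis = 0.25) {
  sc <- scene(scatterers(x = x, y = y, z = z,
                         amplitude = scattering_amplitude(geometry, z, vis)))
  raw <- simulate_hologram(sc, geometry, noise_std = noise_std, seed = seed,
                           on_undersampled = "none")
  bg <- simulate_background(geometry, noise_std = noise_std,
                            seed = seed + 7919L)
  contrast_hologram(raw, bg)
}

# Lateral position (um) of the intensity arg-max of a reconstructed field.
argmax_position <- function(field) {
  I <- Mod(field$values)^2
  pk <- which(I == max(I), arr.ind = TRUE)[1, ]
  nr <- nrow(I)
  nc <- ncol(I)
  c(
    x = unname(((pk["col"] - 0.5) - nc / 2) * field$object_pixel),
    y = unname(((pk["row"] - 0.5) - nr / 2) * field$object_pixel)
  )
}
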