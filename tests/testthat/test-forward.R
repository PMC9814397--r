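test_that("reference wave is a unit-strength spherical wave", {
  g <- bench_geometry()
  a <- reference_wave(g, c(0, 0, 5000))
  expect_equal(Mod(a), 1 / 5000, tolerance = 1e-12)

  # spherical symmetry: equal distance, equal amplitude
  p1 <- c(300, 400, 5000)
  p2 <- c(-400, 300, 5000)
  expect_equal(reference_wave(g, p1), reference_wave(g, p2),
               tolerance = 1e-12)

  # one effective wavelength of extra path advances the phase by 2 pi
  gw <- optical_geometry(medium_index = 1.33)
  r1 <- 5000
  r2 <- 5000 + gw$effective_wavelength
  ph <- Arg(reference_wave(gw, c(0, 0, r2)) / reference_wave(gw, c(0, 0, r1)))
  expect_equal(ph %% (2 * pi), 0, tolerance = 1e-6)

  expect_error(reference_wave(g, c(0, 0, 0)), "singular")
})

test_that("an empty scene gives a smooth radially symmetric source profile", {
  g <- crop_geometry(64)
  h <- simulate_hologram(scene(), g, noise_std = 0)
  expect_s3_class(h, "hologram")
  expect_equal(h$kind, "raw")
  expect_true(all(h$pixels >= 0))
  expect_equal(mean(h$pixels), 100, tolerance = 1e-9) # intensity_level
  # four-fold symmetry of |A_ref|^2 about the sensor centre
  expect_equal(h$pixels, h$pixels[64:1, ], tolerance = 1e-9)
  expect_equal(h$pixels, h$pixels[, 64:1], tolerance = 1e-9)
  # no fringes: monotone decay along the positive x axis
  expect_true(all(diff(h$pixels[32, 33:64]) < 0))
})

test_that("fringe ring count matches the two-wave interference model", {
  g <- crop_geometry(128)
  z0 <- 40
  ctr <- point_contrast(g, z = z0, vis = 0.1)
  mid <- 64
  profile <- ctr$pixels[mid, (mid + 1):128]

  # independent oracle: the radial fringe phase of reference vs scattered
  # spherical waves, evaluated at the same pixel centres
  co <- sensor_coordinates(g)
  rho <- co$x[(mid + 1):128]
  y0 <- co$y[mid]
  k <- g$wavenumber
  phase <- k * (z0 + sqrt(rho^2 + y0^2 + (g$distance - z0)^2) -
                  sqrt(rho^2 + y0^2 + g$distance^2))
  oracle_cross <- sum(abs(diff(sign(cos(phase)))) > 0)
  measured_cross <- sum(abs(diff(sign(profile))) > 0)
  expect_lte(abs(measured_cross - oracle_cross), 2)
  expect_gt(measured_cross, 5) # it is a genuine fringe pattern
})

test_that("simulation is deterministic per seed and validates inputs", {
  g <- crop_geometry(32)
  sc <- scene(scatterers(z = 20, amplitude = 5))
  h1 <- simulate_hologram(sc, g, noise_std = 2, seed = 11)
  h2 <- simulate_hologram(sc, g, noise_std = 2, seed = 11)
  h3 <- simulate_hologram(sc, g, noise_std = 2, seed = 12)
  expect_identical(h1$pixels, h2$pixels)
  expect_false(identical(h1$pixels, h3$pixels))
  expect_true(all(h1$pixels >= 0)) # noise clipped at zero

  n1 <- simulate_hologram(sc, g, noise_std = 0)
  n2 <- simulate_hologram(sc, g, noise_std = 0, seed = 99)
  expect_identical(n1$pixels, n2$pixels) # bitwise without noise

  expect_error(simulate_hologram(sc, g, noise_std = -1))
  expect_error(simulate_hologram(scene(scatterers(z = 1e5)), g), "0 < z")
  expect_error(simulate_hologram(scene(scatterers(z = -3)), g), "0 < z")
})

test_that("the scattered field is linear in the scatterers", {
  g <- crop_geometry(32)
  s1 <- scatterers(x = 1, y = 0.5, z = 18, amplitude = 3)
  s2 <- scatterers(x = -0.8, y = -0.3, z = 25, amplitude = 2i)
  f1 <- holotrace:::forward_field(scene(s1), g)
  f2 <- holotrace:::forward_field(scene(s2), g)
  f12 <- holotrace:::forward_field(scene(rbind(s1, s2)), g)
  fref <- holotrace:::forward_field(scene(), g)
  expect_equal(f12 - fref, (f1 - fref) + (f2 - fref), tolerance = 1e-12)

  # independent direct summation at a few pixels
  k <- g$wavenumber
  co <- sensor_coordinates(g)
  for (px in list(c(5L, 9L), c(20L, 30L))) {
    X <- co$x[px[2]]
    Y <- co$y[px[1]]
    rs <- sqrt(1^2 + 0.5^2 + 18^2)
    dist <- sqrt((X - 1)^2 + (Y - 0.5)^2 + (co$z - 18)^2)
    expected <- 3 * exp(1i * k * rs) / rs * exp(1i * k * dist) / dist
    expect_equal(f1[px[1], px[2]] - fref[px[1], px[2]], expected,
                 tolerance = 1e-12)
  }
})

test_that("contrast holograms subtract exactly and retain only fringes", {
  g <- crop_geometry(64)
  bg <- simulate_background(g, noise_std = 0)
  expect_equal(bg$kind, "background")
  expect_gt(mean(bg$pixels), 0)
  # background equals an empty-scene raw hologram exactly
  expect_identical(bg$pixels, simulate_hologram(scene(), g)$pixels)

  zero <- contrast_hologram(bg, bg)
  expect_equal(zero$kind, "contrast")
  expect_true(all(zero$pixels == 0))

  shifted <- hologram(bg$pixels + 7, g, "raw")
  expect_true(all(contrast_hologram(shifted, bg)$pixels == 7))

  raw <- simulate_hologram(scene(scatterers(z = 30,
                                            amplitude = scattering_amplitude(g, 30, 0.15))),
                           g, noise_std = 0)
  ctr <- contrast_hologram(raw, bg)
  expect_lt(mean(abs(ctr$pixels)), 0.2 * mean(raw$pixels))
  expect_gt(max(abs(ctr$pixels)), 0)

  g2 <- crop_geometry(32)
  expect_error(contrast_hologram(raw, simulate_background(g2)), "shape")
})

test_that("undersampled scenes trigger the Nyquist guard", {
  # full-pitch sensor with a deep scatterer: fringes alias at the corners
  g <- optical_geometry(pixel_pitch = 5.5, distance = 625,
                        sensor_shape = c(64, 64))
  sc <- scene(scatterers(z = 400))
  expect_warning(simulate_hologram(sc, g, on_undersampled = "warn"),
                 "undersampled")
  expect_error(simulate_hologram(sc, g, on_undersampled = "error"),
               "undersampled")
  expect_silent(simulate_hologram(sc, g, on_undersampled = "none"))
  # near-pinhole scene is clean
  expect_silent(simulate_hologram(scene(scatterers(z = 12)), g))
})

test_that("discretize_sphere fills the volume with conserved strength", {
  # coarser than the radius: collapses to one point
  one <- discretize_sphere(c(1, 2, 300), diameter = 0.1, spacing = 0.2)
  expect_equal(nrow(one), 1)
  expect_equal(one$x_um, 1)

  s1 <- discretize_sphere(c(0, 0, 500), diameter = 2, spacing = 0.2,
                          amplitude = 10)
  s2 <- discretize_sphere(c(0, 0, 500), diameter = 2, spacing = 0.1,
                          amplitude = 10)
  # total strength invariant under refinement
  expect_equal(Mod(sum(s1$amplitude)), 10, tolerance = 1e-9)
  expect_equal(Mod(sum(s2$amplitude)), 10, tolerance = 1e-9)
  # counts grow as (diameter / spacing)^3 within lattice rounding
  expect_equal(nrow(s2) / nrow(s1), 8, tolerance = 0.15)
  # all points inside the sphere
  expect_true(all(s1$x_um^2 + s1$y_um^2 + (s1$z_um - 500)^2 <= 1.0000001))

  expect_error(discretize_sphere(c(0, 0, 1), diameter = -1, spacing = 0.1))
  expect_error(discretize_sphere(c(0, 0, 1), diameter = 1, spacing = 0))
})
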