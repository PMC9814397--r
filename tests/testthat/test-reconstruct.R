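test_that("degenerate holograms reconstruct trivially", {
  g <- crop_geometry(32)
  zero <- hologram(matrix(0, 32, 32), g, "contrast")
  for (z in c(50, 200, 500)) {
    f <- kh_reconstruct_fast(zero, z)
    expect_true(all(f$values == 0))
    expect_equal(f$object_pixel, 5.5 * z / 625, tolerance = 1e-12)
  }

  # one nonzero sensor pixel: every kernel term has unit modulus, so the
  # reconstructed amplitude is |v| * dA everywhere
  px <- matrix(0, 32, 32)
  px[5, 20] <- 3
  one <- hologram(px, g, "contrast")
  fd <- kh_reconstruct_direct(one, 100)
  ff <- kh_reconstruct_fast(one, 100)
  expect_equal(max(abs(Mod(fd$values) - 3 * 5.5^2)), 0, tolerance = 1e-8)
  expect_equal(max(abs(Mod(ff$values) - 3 * 5.5^2)), 0, tolerance = 1e-6)

  expect_error(kh_reconstruct_fast(one, 0), "inside")
  expect_error(kh_reconstruct_fast(one, 625), "inside")
  expect_warning(kh_reconstruct_fast(
    hologram(px, g, "raw"), 100), "raw")
})

test_that("fast transform equals the direct-summation oracle", {
  set.seed(101)
  sizes <- c(32, 32, 48, 48, 64)
  for (n in sizes) {
    g <- crop_geometry(n)
    px <- matrix(rnorm(n * n), n, n)
    h <- hologram(px, g, "contrast")
    for (z in c(0.1, 0.4, 0.7) * g$distance) {
      fd <- kh_reconstruct_direct(h, z)
      ff <- kh_reconstruct_fast(h, z)
      rel <- sqrt(mean(Mod(ff$values - fd$values)^2)) /
        sqrt(mean(Mod(fd$values)^2))
      expect_lt(rel, 1e-6)
    }
  }
})

test_that("the transform is linear", {
  g <- crop_geometry(32)
  set.seed(5)
  h1 <- hologram(matrix(rnorm(1024), 32, 32), g, "contrast")
  h2 <- hologram(matrix(rnorm(1024), 32, 32), g, "contrast")
  a <- 2.3
  b <- -0.7
  hs <- hologram(a * h1$pixels + b * h2$pixels, g, "contrast")
  z <- 150
  lhs <- kh_reconstruct_fast(hs, z)$values
  rhs <- a * kh_reconstruct_fast(h1, z)$values +
    b * kh_reconstruct_fast(h2, z)$values
  scale <- sqrt(mean(Mod(rhs)^2))
  expect_lt(max(Mod(lhs - rhs)) / scale, 1e-10)
})

test_that("a point scatterer refocuses at its true position", {
  g <- crop_geometry(128)
  z0 <- 30
  x0 <- 0.7
  y0 <- -0.4
  ctr <- point_contrast(g, x = x0, y = y0, z = z0)
  f <- kh_reconstruct_fast(ctr, z0)
  pos <- argmax_position(f)
  expect_lt(abs(pos["x"] - x0), f$object_pixel)
  expect_lt(abs(pos["y"] - y0), f$object_pixel)

  # volume scan: the per-plane maximum peaks at the plane nearest z0
  zs <- seq(20, 40, by = 2)
  st <- reconstruct_volume(ctr, zs)
  score <- vapply(st, function(f) {
    I <- Mod(f$values)^2
    max(I) / mean(I)
  }, numeric(1))
  expect_equal(zs[which.max(score)], zs[which.min(abs(zs - z0))])
})

test_that("reconstruction stacks preserve order and validate input", {
  g <- crop_geometry(32)
  h <- hologram(matrix(rnorm(1024), 32, 32), g, "contrast")
  st <- reconstruct_volume(h, c(50, 100, 150))
  expect_length(st, 3)
  expect_equal(attr(st, "z"), c(50, 100, 150))
  expect_equal(vapply(st, function(f) f$z, numeric(1)), c(50, 100, 150))
  expect_length(reconstruct_volume(h, numeric(0)), 0)
  expect_error(reconstruct_volume(h, c(100, 50)), "increasing")
  expect_error(reconstruct_volume(h, c(50, 50)), "increasing")
})

test_that("field views satisfy their algebraic identities", {
  g <- crop_geometry(32)
  v <- matrix(complex(real = rnorm(1024), imaginary = rnorm(1024)), 32, 32)
  v[1, 1] <- 0 + 0i # zero amplitude: phase defined as 0
  v[2, 2] <- 5 + 0i # real positive: phase 0
  v[3, 3] <- -1 + 0i # boundary: arg = pi, not -pi
  f <- reconstructed_field(v, 100, g)
  vw <- field_views(f)
  expect_equal(vw$intensity, vw$amplitude^2, tolerance = 1e-12)
  expect_true(all(vw$phase > -pi & vw$phase <= pi))
  expect_equal(vw$phase[1, 1], 0)
  expect_equal(vw$phase[2, 2], 0)
  expect_equal(vw$phase[3, 3], pi)
})

test_that("the focused spot width is near the diffraction limit", {
  g <- crop_geometry(256)
  z0 <- 12
  ctr <- point_contrast(g, x = 0.8, y = -0.5, z = z0)
  f <- kh_reconstruct_fast(ctr, z0)
  I <- field_views(f)$intensity
  pk <- which(I == max(I), arr.ind = TRUE)[1, ]
  prof <- crosscut(I, c(pk[1], pk[2] - 8), c(pk[1], pk[2] + 8),
                   f$object_pixel, samples = 401)
  w <- fwhm(prof, baseline = "min")
  expect_gt(w / lateral_resolution(g), 0.8)
  expect_lt(w / lateral_resolution(g), 1.5)
})

test_that("wiener deconvolution sharpens without moving the focus", {
  g <- crop_geometry(128)
  z0 <- 25
  ctr <- point_contrast(g, x = 0.5, y = 0.3, z = z0)
  st <- reconstruct_volume(ctr, c(z0 - 0.5, z0, z0 + 0.5))

  expect_identical(deconvolve(st, "none"), st)
  expect_error(deconvolve(st, "sharpen"))

  dst <- deconvolve(st, "wiener")
  expect_length(dst, 3)
  for (i in 1:3) {
    p0 <- which.max(Mod(st[[i]]$values))
    p1 <- which.max(Mod(dst[[i]]$values))
    d <- c((p1 - 1) %% 128 - (p0 - 1) %% 128,
           (p1 - 1) %/% 128 - (p0 - 1) %/% 128)
    expect_lte(max(abs(d)), 1) # arg-max moves at most one pixel
  }

  # a background (noise-only) plane must not get much noisier
  set.seed(31)
  bgh <- hologram(matrix(rnorm(128 * 128, sd = 0.5), 128, 128), g, "contrast")
  stb <- reconstruct_volume(bgh, c(z0, z0 + 0.5))
  dsb <- deconvolve(stb, "wiener")
  for (i in 1:2) {
    v0 <- stats::var(as.vector(Mod(stb[[i]]$values)^2))
    v1 <- stats::var(as.vector(Mod(dsb[[i]]$values)^2))
    expect_lt(v1, 2 * v0)
  }
})
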