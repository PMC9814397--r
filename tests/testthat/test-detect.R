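# Detection fixtures run in the shot-noise-limited regime: fringe
# visibility 0.25 per particle, sensor noise 10 counts on a 100-count
# reference level.
detect_stack <- function(sc_tbl, g, z_planes, seed = 42) {
  sc <- scene(sc_tbl)
  raw <- simulate_hologram(sc, g, noise_std = 10, seed = seed,
                           on_undersampled = "none")
  bg <- simulate_background(g, noise_std = 10, seed = seed + 1000L)
  reconstruct_volume(contrast_hologram(raw, bg), z_planes)
}

test_that("an empty scene yields no detections", {
  g <- crop_geometry(128)
  st <- detect_stack(scatterers(x = numeric(0), y = numeric(0),
                                z = numeric(0)),
                     g, seq(15, 20, by = 1))
  det <- detect_particles(st)
  expect_equal(nrow(det), 0)
  expect_true(all(c("x_um", "width_um", "mean_phase") %in% names(det)))
})

test_that("well-separated particles are recovered at their true positions", {
  g <- crop_geometry(256)
  dres <- depth_resolution(g)
  truth <- data.frame(x = c(-4, 0.5, 3), y = c(2, -3, 1), z = c(11, 13.5, 16))
  st <- detect_stack(
    scatterers(x = truth$x, y = truth$y, z = truth$z,
               amplitude = scattering_amplitude(g, truth$z)),
    g, seq(10, 18, by = dres / 2)
  )
  det <- detect_particles(st)
  expect_equal(nrow(det), 3)
  det <- det[order(det$z_um), ]
  opx <- g$pixel_pitch * truth$z / g$distance
  expect_true(all(abs(det$x_um - truth$x) <= opx))
  expect_true(all(abs(det$y_um - truth$y) <= opx))
  expect_true(all(abs(det$z_um - truth$z) <= 2 * (dres / 2)))
  # the optical axis dimension exceeds the lateral ones (PSF anisotropy)
  expect_true(all(det$length_um > det$width_um))
})

test_that("axially unresolved pairs merge; resolved pairs split", {
  g <- crop_geometry(256)
  dres <- depth_resolution(g)
  zs <- seq(10, 19.5, by = dres / 2)
  amp <- function(z) scattering_amplitude(g, z)

  near <- detect_stack(scatterers(x = 0.3, y = -0.2, z = c(12, 12.2),
                                  amplitude = amp(c(12, 12.2))), g, zs)
  det_near <- detect_particles(near)
  expect_equal(nrow(det_near), 1)
  # merging preserves the elongation along the optical axis
  expect_gt(det_near$length_um, det_near$width_um)

  far <- detect_stack(scatterers(x = 0.3, y = -0.2, z = c(12, 17),
                                 amplitude = amp(c(12, 17))), g, zs)
  det_far <- detect_particles(far)
  expect_equal(nrow(det_far), 2)
  expect_lt(abs(min(det_far$z_um) - 12), 3 * dres)
  expect_lt(abs(max(det_far$z_um) - 17), 3 * dres)
  # a merged pair is at least as long as either resolved single
  expect_gte(det_near$length_um, max(det_far$length_um) - dres)
})

test_that("raising the threshold never increases the detection count", {
  g <- crop_geometry(128)
  st <- detect_stack(scatterers(x = c(-2, 2), y = c(1, -1), z = c(20, 30),
                                amplitude = scattering_amplitude(g, c(20, 30))),
                     g, seq(16, 34, by = 2))
  counts <- vapply(c(5, 20, 60, 200, 2000),
                   function(ts) nrow(detect_particles(st, threshold_sigma = ts,
                                                      seed_rel = 0)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is invariant under intensity rescaling", {
  g <- crop_geometry(128)
  st <- detect_stack(scatterers(x = 1, y = -1, z = 25,
                                amplitude = scattering_amplitude(g, 25)),
                     g, seq(20, 30, by = 1))
  det1 <- detect_particles(st)
  st2 <- structure(lapply(st, function(f) {
    reconstructed_field(f$values * 37.5, f$z, f$geometry)
  }), class = "reconstruction_stack", z = attr(st, "z"))
  det2 <- detect_particles(st2)
  expect_equal(det1$x_um, det2$x_um)
  expect_equal(det1$z_um, det2$z_um)
  expect_equal(nrow(det1), nrow(det2))
})

test_that("particle_dimensions converts voxel boxes to physical units", {
  one <- data.frame(row = 5, col = 7, plane = 2)
  expect_equal(particle_dimensions(one, 0.25, 0.18),
               c(width = 0.25, height = 0.25, length = 0.18))
  box <- expand.grid(row = 1:2, col = 1:3, plane = 1:5)
  expect_equal(particle_dimensions(box, 0.5, 0.2),
               c(width = 1.5, height = 1.0, length = 1.0))
  expect_error(particle_dimensions(box[0, ], 1, 1), "empty")
})

test_that("dimension summaries match a brute-force oracle", {
  rec1 <- tibble::tibble(width_um = 0.2, height_um = 0.3, length_um = 0.7)
  s1 <- summarize_dimensions(rec1)
  expect_equal(nrow(s1), 3)
  expect_equal(s1$mean_um, c(0.2, 0.3, 0.7))
  expect_equal(s1$median_um, s1$mean_um)
  expect_equal(s1$sd_um, c(0, 0, 0))

  rec3 <- tibble::tibble(width_um = c(0.1, 0.2, 0.3),
                         height_um = c(0.3, 0.2, 0.1),
                         length_um = c(1, 2, 3))
  s3 <- summarize_dimensions(rec3)
  expect_equal(s3$mean_um[s3$axis == "width"], 0.2)
  expect_equal(s3$median_um[s3$axis == "width"], 0.2)

  # percentile oracle: sort and linearly interpolate by hand
  set.seed(4)
  v <- runif(1000)
  recN <- tibble::tibble(width_um = v, height_um = v, length_um = v)
  sN <- summarize_dimensions(recN)
  brute <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(sN$p1_um[1], brute(v, 0.01), tolerance = 1e-12)
  expect_equal(sN$p99_um[1], brute(v, 0.99), tolerance = 1e-12)
  expect_true(all(sN$p1_um <= sN$median_um & sN$median_um <= sN$p99_um))

  # permutation invariance
  sP <- summarize_dimensions(recN[sample(1000), ])
  expect_equal(sP, sN)

  expect_error(summarize_dimensions(recN[0, ]), "no particle")
})

test_that("size distributions count records into the given bins", {
  rec <- tibble::tibble(width_um = c(0.05, 0.12, 0.13, 0.31),
                        height_um = 1, length_um = 1)
  edges <- c(0, 0.1, 0.2, 0.3, 0.4)
  h <- size_distribution(rec, "width", edges)
  expect_equal(h$count, c(1L, 2L, 0L, 1L))
  expect_equal(sum(h$count), 4)

  h0 <- size_distribution(rec[0, ], "width", edges)
  expect_true(all(h0$count == 0))

  one <- size_distribution(tibble::tibble(width_um = c(0.15, 0.11),
                                          height_um = 1, length_um = 1),
                           "width", edges)
  expect_equal(sum(one$count > 0), 1)

  expect_error(size_distribution(rec, "width", c(1, 0.5)), "increasing")
})

test_that("detection recovers random multi-particle scenes", {
  g <- crop_geometry(256)
  dres <- depth_resolution(g)
  set.seed(77)
  tp <- 0
  fp <- 0
  fn <- 0
  for (sim in 1:5) {
    n <- sample(1:6, 1)
    tr <- data.frame(x = runif(n, -5, 5), y = runif(n, -5, 5),
                     z = runif(n, 10.5, 17.5))
    st <- detect_stack(
      scatterers(x = tr$x, y = tr$y, z = tr$z,
                 amplitude = scattering_amplitude(g, tr$z)),
      g, seq(10, 18.2, by = dres / 2), seed = 500 + sim
    )
    det <- detect_particles(st)
    matched <- rep(FALSE, nrow(det))
    for (i in seq_len(n)) {
      if (nrow(det) == 0) {
        fn <- fn + 1
        next
      }
      dd <- sqrt((det$x_um - tr$x[i])^2 + (det$y_um - tr$y[i])^2 +
                   ((det$z_um - tr$z[i]) / 3)^2)
      j <- which.min(ifelse(matched, Inf, dd))
      if (length(j) > 0 && dd[j] < 1.5) {
        tp <- tp + 1
        matched[j] <- TRUE
      } else {
        fn <- fn + 1
      }
    }
    fp <- fp + sum(!matched)
  }
  expect_gte(tp / (tp + fp), 0.95)
  expect_gte(tp / (tp + fn), 0.95)
})
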