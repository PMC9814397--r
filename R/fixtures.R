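#' Specification of a synthetic experiment fixture
#'
#' Describes one of the emulated bench experiments so that scenes,
#' holograms and ground truth can be generated reproducibly:
#'
#' * `psl100` / `psl200`: monodisperse-grade polystyrene latex sphere
#'   aerosols; diameters are drawn from log-normal distributions whose
#'   modes fall in the 100-160 nm and 150-300 nm bands respectively.
#' * `mixed_oxide`: sub-100 nm metal-oxide particles (higher refractive
#'   index, smaller diameters).
#' * `moving_psl`: polystyrene spheres advancing by a fixed velocity
#'   (µm/frame) each frame, recorded as a video.
#' * `background_only`: object-free frames.
#'
#' @param experiment One of `"psl100"`, `"psl200"`, `"mixed_oxide"`,
#'   `"moving_psl"`, `"background_only"`.
#' @param n_particles Number of particles per frame.
#' @param n_frames Number of frames (>= 1).
#' @param frame_rate Frames per second (default 16).
#' @param velocity Length-3 velocity vector, µm/frame (used by
#'   `moving_psl`).
#' @param noise_std Sensor noise standard deviation in camera units
#'   (reference intensity level is 100). The default 10 puts per-pixel
#'   fringe SNR in the shot-noise-limited few-units range of real
#'   nanoparticle holograms.
#' @param intensity_level Mean noiseless reference intensity, camera units.
#' @param visibility Target fringe visibility of each particle (see
#'   [scattering_amplitude()]).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param z_range Depth interval the particles occupy, µm.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(experiment = c("psl100", "psl200", "mixed_oxide",
                                        "moving_psl", "background_only"),
                         n_particles = 10, n_frames = 1, frame_rate = 16,
                         velocity = c(0, 0, 0), noise_std = 10,
                         intensity_level = 100, visibility = 0.25, seed = 1L,
                         z_range = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(n_frames >= 1, frame_rate > 0, length(velocity) == 3,
            noise_std >= 0)
  structure(
    list(experiment = experiment, n_particles = n_particles,
         n_frames = as.integer(n_frames), frame_rate = frame_rate,
         velocity = as.numeric(velocity), noise_std = noise_std,
         intensity_level = intensity_level, visibility = visibility,
         seed = as.integer(seed), z_range = z_range),
    class = "fixture_spec"
  )
}

fixture_diameters <- function(experiment, n) {
  switch(experiment,
    # modes exp(meanlog - sdlog^2): 0.115 um and 0.202 um
    psl100 = stats::rlnorm(n, meanlog = log(0.12), sdlog = 0.2),
    moving_psl = stats::rlnorm(n, meanlog = log(0.12), sdlog = 0.2),
    psl200 = stats::rlnorm(n, meanlog = log(0.21), sdlog = 0.2),
    mixed_oxide = stats::rlnorm(n, meanlog = log(0.055), sdlog = 0.25),
    numeric(0)
  )
}

fixture_index <- function(experiment) {
  switch(experiment,
    mixed_oxide = 2.0, # metal oxides at 405 nm (zinc/iron oxide class)
    1.5983 # polystyrene
  )
}

#' Generate a synthetic experiment: scenes, holograms and ground truth
#'
#' Draws particle positions and diameters per `spec`, simulates the raw
#' hologram sequence (plus one object-free background hologram) and
#' returns the ground-truth particle table alongside, so detection and
#' tracking can be validated end to end. Scatterer positions are drawn
#' uniformly over the central half of the field of view and the requested
#' depth range (default: the middle 40-70% of the source-screen distance);
#' moving particles advance by `velocity` each frame.
#'
#' @param spec A [fixture_spec()].
#' @param geometry An [optical_geometry()]; defaults to the reference
#'   instrument (2048 x 2048 px at 5.5 µm, d = 5 mm, 405 nm).
#' @return A list with elements `scenes` (list of [scene()]s), `sequence`
#'   (a [hologram_sequence()] of raw frames), `background` (a background
#'   [hologram()]), `truth` (tibble: `frame`, `particle_id`, `x_um`,
#'   `y_um`, `z_um`, `diameter_um`, `n_obj`), `geometry`, and `spec`.
#' @examples
#' fx <- generate_fixture(fixture_spec("psl100", n_particles = 3, noise_std = 0),
#'                        optical_geometry(sensor_shape = c(64, 64)))
#' fx$truth
#' @export
generate_fixture <- function(spec, geometry = optical_geometry()) {
  stopifnot(inherits(spec, "fixture_spec"), is_geometry(geometry))
  d <- geometry$distance
  zr <- spec$z_range %||% c(0.4 * d, 0.7 * d)
  n <- if (spec$experiment == "background_only") 0L else spec$n_particles
  half_w <- geometry$screen_width / 4
  half_h <- geometry$screen_height / 4

  truth0 <- with_seed(spec$seed, {
    dia <- fixture_diameters(spec$experiment, n)
    tibble::tibble(
      particle_id = seq_len(n),
      x_um = runif(n, -half_w / 2, half_w / 2) * (zr[1] / d),
      y_um = runif(n, -half_h / 2, half_h / 2) * (zr[1] / d),
      z_um = runif(n, zr[1], zr[2]),
      diameter_um = dia,
      n_obj = fixture_index(spec$experiment)
    )
  })

  scenes <- vector("list", spec$n_frames)
  truth <- vector("list", spec$n_frames)
  for (f in seq_len(spec$n_frames)) {
    shift <- (f - 1) * spec$velocity
    tf <- dplyr::mutate(truth0,
                        x_um = .data$x_um + shift[1],
                        y_um = .data$y_um + shift[2],
                        z_um = .data$z_um + shift[3],
                        frame = f - 1L)
    if (n > 0 && any(tf$z_um <= 0 | tf$z_um >= d)) {
      stop("fixture particles leave the volume (0, d) at frame ", f - 1)
    }
    scenes[[f]] <- scene(
      scatterers(tf$x_um, tf$y_um, tf$z_um, tf$diameter_um, tf$n_obj,
                 amplitude = scattering_amplitude(geometry, tf$z_um,
                                                  spec$visibility %||% 0.25)),
      frame_time = (f - 1) / spec$frame_rate
    )
    truth[[f]] <- tf
  }

  holos <- lapply(seq_len(spec$n_frames), function(f) {
    h <- simulate_hologram(scenes[[f]], geometry, noise_std = spec$noise_std,
                           seed = spec$seed + f,
                           intensity_level = spec$intensity_level,
                           on_undersampled = "none")
    h$frame_index <- f - 1L
    h$frame_time <- (f - 1) / spec$frame_rate
    h
  })
  background <- simulate_background(geometry, noise_std = spec$noise_std,
                                    seed = spec$seed,
                                    intensity_level = spec$intensity_level)
  list(
    scenes = scenes,
    sequence = hologram_sequence(holos, spec$frame_rate),
    background = background,
    truth = if (spec$n_frames == 1 && n == 0) {
      tibble::tibble(frame = integer(), particle_id = integer(),
                     x_um = numeric(), y_um = numeric(), z_um = numeric(),
                     diameter_um = numeric(), n_obj = numeric())
    } else {
      dplyr::bind_rows(truth)
    },
    geometry = geometry,
    spec = spec
  )
}
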