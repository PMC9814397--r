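#' Hologram time sequence
#'
#' An ordered list of holograms sharing one geometry, recorded at a fixed
#' frame rate; frame times satisfy `t = frame_index / frame_rate`.
#'
#' @param holograms List of [hologram()]s with constant geometry.
#' @param frame_rate Frames per second (default 16; the frame interval is
#'   then 62.5 ms).
#' @return An object of class `hologram_sequence`.
#' @export
hologram_sequence <- function(holograms, frame_rate = 16) {
  stopifnot(is.list(holograms), length(holograms) >= 1, frame_rate > 0)
  if (!all(vapply(holograms, is_hologram, logical(1)))) {
    stop("all elements must be holograms")
  }
  shp <- dim(holograms[[1]]$pixels)
  if (!all(vapply(holograms, function(h) all(dim(h$pixels) == shp), logical(1)))) {
    stop("all holograms must share the sensor shape")
  }
  fi <- vapply(holograms, function(h) h$frame_index, integer(1))
  if (any(diff(fi) <= 0)) {
    # renumber 0..n-1 when indices were not provided
    for (i in seq_along(holograms)) {
      holograms[[i]]$frame_index <- i - 1L
      holograms[[i]]$frame_time <- (i - 1) / frame_rate
    }
  }
  structure(holograms, class = "hologram_sequence", frame_rate = frame_rate)
}

#' @export
print.hologram_sequence <- function(x, ...) {
  cat(sprintf("<hologram_sequence: %d frame(s) at %g fps (dt = %g ms)>\n",
              length(x), attr(x, "frame_rate"),
              1000 / attr(x, "frame_rate")))
  invisible(x)
}

#' Consecutive-frame difference sequence
#'
#' Subtracts each hologram from its successor, producing `n - 1` contrast
#' frames in which all static content (background, holder artefacts,
#' stationary particles) cancels exactly and only moving objects remain.
#'
#' @param seq A [hologram_sequence()] with at least 2 frames.
#' @return A [hologram_sequence()] of contrast holograms, length `n - 1`.
#' @export
difference_sequence <- function(seq) {
  stopifnot(inherits(seq, "hologram_sequence"))
  if (length(seq) < 2) stop("need at least 2 frames to difference")
  fr <- attr(seq, "frame_rate")
  out <- lapply(seq_len(length(seq) - 1), function(i) {
    h <- hologram(seq[[i + 1]]$pixels - seq[[i]]$pixels,
                  seq[[i + 1]]$geometry, "contrast",
                  frame_index = seq[[i + 1]]$frame_index,
                  frame_time = seq[[i + 1]]$frame_time)
    h
  })
  structure(out, class = "hologram_sequence", frame_rate = fr)
}

#' Summed trajectory map at a fixed plane
#'
#' Reconstructs each difference frame at one plane `z` and sums the
#' intensities. A particle moving through the volume appears as a chain of
#' bright spots marking its successive positions; spots fade as the
#' particle moves out of the chosen plane.
#'
#' @param diff_seq A [hologram_sequence()] of contrast (difference) frames.
#' @param z Reconstruction plane, µm.
#' @param n_frames Number of leading frames to sum (default: all).
#' @return A real matrix (summed intensity), with attribute `z`.
#' @export
trajectory_map <- function(diff_seq, z, n_frames = length(diff_seq)) {
  stopifnot(inherits(diff_seq, "hologram_sequence"))
  if (n_frames > length(diff_seq)) {
    stop("n_frames exceeds the number of difference frames")
  }
  if (n_frames == 0) {
    g <- diff_seq[[1]]$geometry
    m <- matrix(0, g$sensor_shape[1], g$sensor_shape[2])
    attr(m, "z") <- z
    return(m)
  }
  acc <- NULL
  for (i in seq_len(n_frames)) {
    f <- kh_reconstruct_fast(diff_seq[[i]], z)
    I <- Mod(f$values)^2
    acc <- if (is.null(acc)) I else acc + I
  }
  attr(acc, "z") <- z
  attr(acc, "object_pixel") <- diff_seq[[1]]$geometry$pixel_pitch * z /
    diff_seq[[1]]$geometry$distance
  acc
}

#' Local maxima of a 2D map
#'
#' Finds pixels that are strict maxima within a square neighbourhood and
#' exceed a relative intensity floor — used to count the spots of a
#' trajectory map.
#'
#' @param map Real matrix.
#' @param min_distance Neighbourhood radius in pixels.
#' @param threshold_rel Keep maxima above `threshold_rel * max(map)`.
#' @return Tibble with columns `row`, `col`, `value`.
#' @export
local_maxima <- function(map, min_distance = 3, threshold_rel = 0.1) {
  stopifnot(is.matrix(map))
  thr <- threshold_rel * max(map)
  nr <- nrow(map)
  nc <- ncol(map)
  cand <- which(map > thr)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    r <- (cand[i] - 1) %% nr + 1
    c <- (cand[i] - 1) %/% nr + 1
    rs <- max(1, r - min_distance):min(nr, r + min_distance)
    cs <- max(1, c - min_distance):min(nc, c + min_distance)
    keep[i] <- map[r, c] >= max(map[rs, cs]) &&
      sum(map[rs, cs] == map[r, c]) == 1
  }
  cand <- cand[keep]
  tibble::tibble(
    row = (cand - 1) %% nr + 1,
    col = (cand - 1) %/% nr + 1,
    value = map[cand]
  )
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: at each transition,
#' candidate (track head, detection) pairs closer than `max_step` are
#' linked in order of increasing 3D distance (ties broken by lower
#' detection index); unmatched detections start new tracks. Deterministic
#' for a given input order.
#'
#' @param per_frame_detections List of detection tibbles (one per frame,
#'   as from [detect_particles()]; may be empty).
#' @param max_step Maximum 3D link distance, µm.
#' @param frame_rate Frames per second used for time stamps.
#' @return A tibble with columns `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, `z_um`.
#' @export
link_tracks <- function(per_frame_detections, max_step, frame_rate = 16) {
  if (max_step <= 0) stop("max_step must be positive")
  n <- length(per_frame_detections)
  if (n == 0) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          t_s = numeric(), x_um = numeric(), y_um = numeric(),
                          z_um = numeric()))
  }
  rows <- list()
  heads <- NULL # tibble: track_id, x, y, z
  next_id <- 1L
  for (f in seq_len(n)) {
    det <- per_frame_detections[[f]]
    ndet <- if (is.null(det)) 0L else nrow(det)
    assigned_det <- integer(0)
    new_heads <- NULL
    if (ndet > 0 && !is.null(heads) && nrow(heads) > 0) {
      dmat <- outer(heads$x_um, det$x_um, "-")^2 +
        outer(heads$y_um, det$y_um, "-")^2 +
        outer(heads$z_um, det$z_um, "-")^2
      dmat <- sqrt(dmat)
      cand <- which(dmat <= max_step, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(dmat[cand], cand[, 2], cand[, 1])
        cand <- cand[ord, , drop = FALSE]
        used_h <- logical(nrow(heads))
        used_d <- logical(ndet)
        for (i in seq_len(nrow(cand))) {
          hh <- cand[i, 1]
          dd <- cand[i, 2]
          if (used_h[hh] || used_d[dd]) next
          used_h[hh] <- TRUE
          used_d[dd] <- TRUE
          id <- heads$track_id[hh]
          rows[[length(rows) + 1]] <- tibble::tibble(
            track_id = id, frame = f - 1L, t_s = (f - 1) / frame_rate,
            x_um = det$x_um[dd], y_um = det$y_um[dd], z_um = det$z_um[dd]
          )
          new_heads <- dplyr::bind_rows(new_heads, tibble::tibble(
            track_id = id, x_um = det$x_um[dd], y_um = det$y_um[dd],
            z_um = det$z_um[dd]
          ))
          assigned_det <- c(assigned_det, dd)
        }
      }
    }
    if (ndet > 0) {
      for (dd in setdiff(seq_len(ndet), assigned_det)) {
        id <- next_id
        next_id <- next_id + 1L
        rows[[length(rows) + 1]] <- tibble::tibble(
          track_id = id, frame = f - 1L, t_s = (f - 1) / frame_rate,
          x_um = det$x_um[dd], y_um = det$y_um[dd], z_um = det$z_um[dd]
        )
        new_heads <- dplyr::bind_rows(new_heads, tibble::tibble(
          track_id = id, x_um = det$x_um[dd], y_um = det$y_um[dd],
          z_um = det$z_um[dd]
        ))
      }
    }
    heads <- new_heads # tracks with no match this frame terminate
  }
  if (length(rows) == 0) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          t_s = numeric(), x_um = numeric(), y_um = numeric(),
                          z_um = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$track_id, .data$frame)
}

#' Kinematic summary of one track
#'
#' @param track Tibble with columns `frame`, `x_um`, `y_um`, `z_um` (one
#'   track, >= 2 points).
#' @param frame_rate Frames per second.
#' @return One-row tibble: `n_points`, `duration_s`, `path_length_um`,
#'   `net_displacement_um`, `mean_speed_um_s`, `straightness` (net/path, in
#'   \[0, 1\]).
#' @export
track_kinematics <- function(track, frame_rate = 16) {
  if (nrow(track) < 2) stop("track needs at least 2 points")
  track <- dplyr::arrange(track, .data$frame)
  p <- as.matrix(track[, c("x_um", "y_um", "z_um")])
  steps <- sqrt(rowSums(diff(p)^2))
  path <- sum(steps)
  net <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  duration <- (track$frame[nrow(track)] - track$frame[1]) / frame_rate
  tibble::tibble(
    n_points = nrow(track),
    duration_s = duration,
    path_length_um = path,
    net_displacement_um = net,
    mean_speed_um_s = path / duration,
    straightness = if (path > 0) net / path else 1
  )
}
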