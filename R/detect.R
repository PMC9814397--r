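#' Detect particles in a reconstruction stack
#'
#' Particle detection proceeds in three stages, the standard scheme for
#' focal stacks whose background is structured diffraction rather than
#' plain noise:
#'
#' 1. Every plane is standardized by its own robust background statistics
#'    (`(I - median) / MAD`); the overall reconstruction scale varies
#'    strongly with depth, so plane-local rather than stack-global
#'    statistics are used. Voxels scoring above `threshold_sigma` are
#'    candidates.
#' 2. 3D local maxima (26-neighbourhood) among the candidates are particle
#'    seeds; weaker maxima within `nms_radius_xy` pixels laterally *and*
#'    `nms_radius_z` planes axially of a stronger seed are suppressed
#'    (these are defocus sidelobes of the stronger particle).
#' 3. Each seed is grown by 26-connectivity over voxels above half its
#'    peak score, so the reported bounding box is a full-width-at-half-
#'    maximum box — the same convention used to size particles from
#'    crosscuts. Regions smaller than `min_voxels` are dropped.
#'
#' Lateral physical units use each region's peak-plane object pixel; axial
#' units use the stack plane spacing. The axial extent is reported as
#' `length_um` (the optical-axis dimension): particles closer together
#' along z than the depth resolution merge into a single, axially
#' elongated detection, which is why lengths tend to exceed lateral
#' widths.
#'
#' @param stack A `reconstruction_stack` from [reconstruct_volume()], at
#'   least 2 planes for meaningful 3D extents (a single plane is accepted
#'   with a warning; the axial extent is then floored at the nominal depth
#'   resolution).
#' @param threshold_sigma Detection floor in robust per-plane MAD units.
#' @param min_voxels Minimum half-max region size kept.
#' @param nms_radius_xy,nms_radius_z Non-maximum-suppression radius in
#'   pixels (lateral) and planes (axial).
#' @param seed_rel Relative seed cut: seeds scoring below `seed_rel` times
#'   the strongest seed are discarded (defocus ghosts and pair-interference
#'   artefacts score far below genuine foci). Set to 0 to disable.
#' @param frame_index Frame number recorded in the `frame` column.
#' @return A tibble with columns `frame`, `x_um`, `y_um`, `z_um`,
#'   `width_um`, `height_um`, `length_um`, `peak_intensity`, `mean_phase`,
#'   `voxel_count`.
#' @export
detect_particles <- function(stack, threshold_sigma = 20, min_voxels = 4,
                             nms_radius_xy = 6, nms_radius_z = 6,
                             seed_rel = 0.15, frame_index = 0L) {
  if (!is_stack(stack)) stop("stack must be a reconstruction_stack")
  if (length(stack) == 0) stop("stack is empty")
  z <- attr(stack, "z")
  geometry <- stack[[1]]$geometry
  nr <- nrow(stack[[1]]$values)
  nc <- ncol(stack[[1]]$values)
  np <- length(stack)
  if (np < 2) {
    warning("single-plane stack: axial extents floored at the depth resolution")
    plane_spacing <- depth_resolution(geometry)
  } else {
    plane_spacing <- stats::median(diff(z))
  }

  I <- array(0, dim = c(nr, nc, np))
  S <- array(0, dim = c(nr, nc, np)) # robust per-plane z-score
  P <- array(0, dim = c(nr, nc, np))
  for (i in seq_len(np)) {
    v <- field_views(stack[[i]])
    I[, , i] <- v$intensity
    m <- stats::median(v$intensity)
    s <- stats::mad(v$intensity)
    S[, , i] <- if (s > 0) (v$intensity - m) / s else 0
    P[, , i] <- v$phase
  }
  empty <- tibble::tibble(
    frame = integer(), x_um = numeric(), y_um = numeric(), z_um = numeric(),
    width_um = numeric(), height_um = numeric(), length_um = numeric(),
    peak_intensity = numeric(), mean_phase = numeric(), voxel_count = integer()
  )
  cand <- which(S > threshold_sigma)
  if (length(cand) == 0) return(empty)

  # stage 2: local maxima among candidates, then non-maximum suppression
  pos <- cbind(
    r = (cand - 1) %% nr + 1,
    c = ((cand - 1) %/% nr) %% nc + 1,
    p = (cand - 1) %/% (nr * nc) + 1
  )
  is_max <- vapply(seq_along(cand), function(i) {
    r <- pos[i, 1]; c <- pos[i, 2]; p <- pos[i, 3]
    nb <- S[max(1, r - 1):min(nr, r + 1),
            max(1, c - 1):min(nc, c + 1),
            max(1, p - 1):min(np, p + 1)]
    S[r, c, p] >= max(nb)
  }, logical(1))
  seeds <- cand[is_max]
  spos <- pos[is_max, , drop = FALSE]
  strong <- S[seeds] >= seed_rel * max(S[seeds])
  seeds <- seeds[strong]
  spos <- spos[strong, , drop = FALSE]
  ord <- order(S[seeds], decreasing = TRUE)
  seeds <- seeds[ord]
  spos <- spos[ord, , drop = FALSE]
  keep <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    if (i == 1) {
      keep[1] <- TRUE
      next
    }
    kk <- which(keep[seq_len(i - 1)])
    close_xy <- abs(spos[kk, 1] - spos[i, 1]) <= nms_radius_xy &
      abs(spos[kk, 2] - spos[i, 2]) <= nms_radius_xy
    close_z <- abs(spos[kk, 3] - spos[i, 3]) <= nms_radius_z
    keep[i] <- !any(close_xy & close_z)
  }
  seeds <- seeds[keep]
  spos <- spos[keep, , drop = FALSE]

  # stage 3: half-max region growing, strongest seed claims voxels first
  claimed <- array(FALSE, dim = dim(S))
  recs <- list()
  for (i in seq_along(seeds)) {
    pk <- spos[i, ]
    if (claimed[pk[1], pk[2], pk[3]]) next
    floor_s <- max(S[seeds[i]] / 2, threshold_sigma)
    reg <- grow_region_26(S, pk, floor_s, claimed)
    if (nrow(reg) < min_voxels) next
    claimed[cbind(reg$row, reg$col, reg$plane)] <- TRUE
    zc <- z[reg$plane]
    dx <- geometry$pixel_pitch * zc / geometry$distance # per-voxel pitch
    xv <- ((reg$col - 0.5) - nc / 2) * dx
    yv <- ((reg$row - 0.5) - nr / 2) * dx
    w <- S[cbind(reg$row, reg$col, reg$plane)]
    ph <- P[cbind(reg$row, reg$col, reg$plane)]
    dims <- particle_dimensions(
      reg,
      object_pixel = geometry$pixel_pitch * z[pk[3]] / geometry$distance,
      plane_spacing = plane_spacing
    )
    recs[[length(recs) + 1]] <- tibble::tibble(
      frame = as.integer(frame_index),
      x_um = sum(xv * w) / sum(w),
      y_um = sum(yv * w) / sum(w),
      z_um = sum(zc * w) / sum(w),
      width_um = dims[["width"]],
      height_um = dims[["height"]],
      length_um = dims[["length"]],
      peak_intensity = I[pk[1], pk[2], pk[3]],
      mean_phase = atan2(sum(w * sin(ph)), sum(w * cos(ph))),
      voxel_count = nrow(reg)
    )
  }
  if (length(recs) == 0) return(empty)
  out <- dplyr::bind_rows(recs)
  dplyr::arrange(out, .data$z_um, .data$y_um, .data$x_um)
}

# Flood fill (26-connectivity) from a peak voxel over S >= floor_s,
# stopping at already-claimed voxels.
grow_region_26 <- function(S, pk, floor_s, claimed) {
  dims <- dim(S)
  frontier <- matrix(pk, nrow = 1)
  seen <- new.env(parent = emptyenv())
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  assign(key(frontier), TRUE, envir = seen)
  acc <- frontier
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, dp = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (nrow(frontier) > 0) {
    nxt <- NULL
    for (j in seq_len(nrow(frontier))) {
      nb <- sweep(offs, 2, frontier[j, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) next
      ks <- key(nb)
      new <- !vapply(ks, function(k) exists(k, envir = seen), logical(1))
      nb <- nb[new, , drop = FALSE]
      ks <- ks[new]
      if (nrow(nb) == 0) next
      for (k in ks) assign(k, TRUE, envir = seen)
      val <- S[nb]
      good <- val >= floor_s & !claimed[nb]
      nb <- nb[good, , drop = FALSE]
      if (nrow(nb) > 0) nxt <- rbind(nxt, nb)
    }
    if (!is.null(nxt)) acc <- rbind(acc, nxt)
    frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 3) else nxt
  }
  data.frame(row = acc[, 1], col = acc[, 2], plane = acc[, 3])
}

#' Bounding-box dimensions of a voxel component
#'
#' Axis-aligned extents of a set of voxels: `width` along x (columns),
#' `height` along y (rows) — the lateral axes — and `length` along z (the
#' optical axis, planes). The axial dimension is deliberately mapped to
#' "length": axial merging of unresolved particles inflates this axis.
#'
#' @param voxels Data frame with columns `row`, `col`, `plane`.
#' @param object_pixel Lateral pixel size, µm.
#' @param plane_spacing Axial plane spacing, µm.
#' @return Named numeric vector `c(width, height, length)` in µm.
#' @export
particle_dimensions <- function(voxels, object_pixel, plane_spacing) {
  if (is.null(nrow(voxels)) || nrow(voxels) == 0) {
    stop("empty voxel set")
  }
  c(
    width = (diff(range(voxels$col)) + 1) * object_pixel,
    height = (diff(range(voxels$row)) + 1) * object_pixel,
    length = (diff(range(voxels$plane)) + 1) * plane_spacing
  )
}

#' Descriptive statistics of detected particle dimensions
#'
#' Per-axis mean, sample SD, median, and 1st/99th percentiles (linear
#' interpolation) of the width/height/length columns of a detection table.
#'
#' @param records Detection tibble from [detect_particles()] (>= 1 row).
#' @return A tibble with one row per axis (`width`, `height`, `length`) and
#'   columns `mean_um`, `sd_um`, `median_um`, `p1_um`, `p99_um`,
#'   `n_particles`.
#' @export
summarize_dimensions <- function(records) {
  if (nrow(records) == 0) stop("no particle records to summarize")
  axes <- c(width = "width_um", height = "height_um", length = "length_um")
  purrr::map_dfr(names(axes), function(a) {
    v <- records[[axes[[a]]]]
    q <- stats::quantile(v, c(0.01, 0.5, 0.99), type = 7, names = FALSE)
    tibble::tibble(
      axis = a, mean_um = mean(v),
      sd_um = if (length(v) > 1) stats::sd(v) else 0,
      median_um = q[2], p1_um = q[1], p99_um = q[3],
      n_particles = nrow(records)
    )
  })
}

#' Histogram of particle sizes along one axis
#'
#' @param records Detection tibble from [detect_particles()].
#' @param axis `"width"`, `"height"` or `"length"`.
#' @param bin_edges Strictly increasing bin edges, µm.
#' @return A tibble with columns `bin_low_um`, `bin_high_um`, `count`;
#'   counts sum to the number of in-range records.
#' @export
size_distribution <- function(records, axis = c("width", "height", "length"),
                              bin_edges) {
  axis <- match.arg(axis)
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing")
  }
  v <- records[[paste0(axis, "_um")]]
  cnt <- if (length(v) == 0) {
    integer(length(bin_edges) - 1)
  } else {
    h <- graphics::hist(v[v >= bin_edges[1] & v <= bin_edges[length(bin_edges)]],
                        breaks = bin_edges, plot = FALSE)
    h$counts
  }
  tibble::tibble(
    bin_low_um = utils::head(bin_edges, -1),
    bin_high_um = utils::tail(bin_edges, -1),
    count = as.integer(cnt)
  )
}
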