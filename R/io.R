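geometry_to_list <- function(g) {
  list(wavelength = g$wavelength, medium_index = g$medium_index,
       distance = g$distance, pixel_pitch = g$pixel_pitch,
       sensor_shape = g$sensor_shape)
}

geometry_from_list <- function(l) {
  req <- c("wavelength", "medium_index", "distance", "pixel_pitch",
           "sensor_shape")
  miss <- setdiff(req, names(l))
  if (length(miss) > 0) {
    stop("sidecar is missing required geometry fields: ",
         paste(miss, collapse = ", "))
  }
  optical_geometry(l$wavelength, l$medium_index, l$distance, l$pixel_pitch,
                   unlist(l$sensor_shape))
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

# Write a file atomically: write to a temporary sibling, then rename.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", "tmp",
                                                           basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

#' Write a hologram to disk (raster + JSON sidecar)
#'
#' Stores the pixel grid as 16-bit grayscale TIFF or 8-bit grayscale PNG
#' (by file extension) plus a JSON sidecar with the same basename holding
#' the optical geometry, kind, frame metadata and the linear value
#' transform `value = raster * value_scale + value_offset` needed to
#' recover the original intensities. Integer-valued grids within the
#' raster's code range are stored losslessly; TIFF is the canonical
#' lossless format for camera data. Both files are written atomically.
#'
#' @param holo A [hologram()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_hologram <- function(holo, path) {
  stopifnot(is_hologram(holo))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff", "png")) {
    stop("unsupported extension: .", ext, " (use .tiff or .png)")
  }
  px <- holo$pixels
  bits <- if (ext == "png") 8L else 16L
  maxcode <- 2^bits - 1
  offset <- min(px, 0)
  rng <- max(px) - offset
  integral <- offset == 0 && rng <= maxcode && all(px == round(px))
  scale <- if (integral) 1 else if (rng > 0) rng / maxcode else 1
  code <- round((px - offset) / scale)
  meta <- c(geometry_to_list(holo$geometry),
            list(kind = holo$kind, frame_index = holo$frame_index,
                 frame_time = holo$frame_time,
                 value_scale = scale, value_offset = offset, bits = bits))
  atomic_write(path, function(tmp) {
    if (ext == "png") {
      png::writePNG(code / maxcode, tmp)
    } else {
      tiff::writeTIFF(code / maxcode, tmp, bits.per.sample = 16,
                      compression = "none")
    }
  })
  atomic_write(sidecar_path(path), function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' Read a hologram written by [write_hologram()]
#'
#' Accepts 8- or 16-bit grayscale TIFF or PNG with the mandatory JSON
#' sidecar; 8-bit input is upcast to the internal real grid without value
#' change. RGB rasters are rejected.
#'
#' @param path Raster path.
#' @return A [hologram()].
#' @export
read_hologram <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("missing sidecar ", sp, "; required fields: wavelength, ",
         "medium_index, distance, pixel_pitch, sensor_shape, kind, ",
         "frame_index, frame_time, value_scale, value_offset")
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3) stop("RGB input not supported: ", path)
  g <- geometry_from_list(meta)
  maxcode <- if (identical(meta$bits, 8L) || identical(meta$bits, 8)) 255 else 65535
  px <- round(img * maxcode) * (meta$value_scale %||% 1) +
    (meta$value_offset %||% 0)
  hologram(px, g, meta$kind %||% "raw",
           frame_index = meta$frame_index %||% 0L,
           frame_time = meta$frame_time %||% 0)
}

#' Read a hologram sequence from numbered files or a multi-page TIFF
#'
#' @param paths Character vector of raster paths in frame order, or a
#'   single multi-page TIFF (its sidecar then describes the shared
#'   geometry).
#' @param frame_rate Frames per second.
#' @return A [hologram_sequence()].
#' @export
read_sequence <- function(paths, frame_rate = 16) {
  stopifnot(length(paths) >= 1)
  if (length(paths) == 1 && tolower(tools::file_ext(paths)) %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    if (length(pages) > 1) {
      meta <- jsonlite::read_json(sidecar_path(paths), simplifyVector = TRUE)
      g <- geometry_from_list(meta)
      maxcode <- 2^(meta$bits %||% 16) - 1
      hs <- lapply(seq_along(pages), function(i) {
        hologram(round(pages[[i]] * maxcode) * (meta$value_scale %||% 1) +
                   (meta$value_offset %||% 0), g, meta$kind %||% "raw",
                 frame_index = i - 1L, frame_time = (i - 1) / frame_rate)
      })
      return(hologram_sequence(hs, frame_rate))
    }
  }
  hs <- lapply(paths, read_hologram)
  fi <- vapply(hs, function(h) h$frame_index, integer(1))
  if (any(diff(fi) <= 0)) stop("non-monotonic frame numbering in sequence")
  for (i in seq_along(hs)) hs[[i]]$frame_time <- hs[[i]]$frame_index / frame_rate
  hologram_sequence(hs, frame_rate)
}

#' Export / import detection and track tables as CSV
#'
#' Column names embed units (`_um`, `_s`) so they survive round trips
#' unambiguously; a header row is always written, even for empty tables.
#' Writes are atomic.
#'
#' @param records Detection tibble from [detect_particles()].
#' @param tracks Track tibble from [link_tracks()].
#' @param path Output CSV path.
#' @return `path` invisibly (exports); a tibble (imports).
#' @export
export_detections <- function(records, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(records, tmp, row.names = FALSE)
  })
}

#' @rdname export_detections
#' @export
read_detections <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname export_detections
#' @export
export_tracks <- function(tracks, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(tracks, tmp, row.names = FALSE)
  })
}

#' @rdname export_detections
#' @export
read_tracks <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write reconstructed views as 32-bit float TIFF
#'
#' @param field A [reconstructed_field()].
#' @param path Output TIFF path.
#' @param view `"intensity"`, `"amplitude"` or `"phase"`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, view = c("intensity", "amplitude", "phase")) {
  view <- match.arg(view)
  v <- field_views(field)[[view]]
  atomic_write(path, function(tmp) {
    tiff::writeTIFF(v, tmp, bits.per.sample = 32, reduce = FALSE)
  })
}

#' Read and validate a run configuration
#'
#' A run configuration is a JSON document holding the optical geometry plus
#' optional reconstruction, detection and tracking settings; unknown keys
#' are rejected to prevent silent typos.
#'
#' @param path JSON path.
#' @return A list with elements `geometry` (an [optical_geometry()]) and
#'   any of `reconstruction`, `detection`, `tracking`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("geometry", "reconstruction", "detection", "tracking", "seed",
               "verbosity")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown run-config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$geometry)) stop("run config must contain 'geometry'")
  cfg$geometry <- geometry_from_list(cfg$geometry)
  cfg
}
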