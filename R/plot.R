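raster_tibble <- function(m, pixel = 1) {
  tibble::tibble(
    x = rep((seq_len(ncol(m)) - 0.5) * pixel, each = nrow(m)),
    y = rep((seq_len(nrow(m)) - 0.5) * pixel, times = ncol(m)),
    value = as.vector(m)
  )
}

#' Plot a hologram
#'
#' @param object A [hologram()].
#' @param downsample Keep every n-th pixel (large sensors plot slowly).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hologram <- function(object, downsample = NULL, ...) {
  px <- object$pixels
  if (is.null(downsample)) downsample <- max(1L, floor(nrow(px) / 512))
  if (downsample > 1) {
    px <- px[seq(1, nrow(px), by = downsample),
             seq(1, ncol(px), by = downsample)]
  }
  df <- raster_tibble(px, object$geometry$pixel_pitch * downsample)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [µm]", y = "y [µm]", fill = "counts",
                  title = sprintf("%s hologram", object$kind))
}

#' Plot a reconstructed field view
#'
#' @param object A [reconstructed_field()].
#' @param view `"intensity"`, `"amplitude"` or `"phase"`.
#' @inheritParams autoplot.hologram
#' @return A ggplot object.
#' @export
autoplot.reconstructed_field <- function(object,
                                         view = c("intensity", "amplitude",
                                                  "phase"),
                                         downsample = NULL, ...) {
  view <- match.arg(view)
  m <- field_views(object)[[view]]
  if (is.null(downsample)) downsample <- max(1L, floor(nrow(m) / 512))
  if (downsample > 1) {
    m <- m[seq(1, nrow(m), by = downsample), seq(1, ncol(m), by = downsample)]
  }
  df <- raster_tibble(m, object$object_pixel * downsample)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [µm]", y = "y [µm]", fill = view,
                  title = sprintf("%s at z = %g µm", view, object$z))
  if (view == "phase") {
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                      high = "red")
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}

#' Plot a summed trajectory map
#'
#' @param map Matrix from [trajectory_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_trajectory_map <- function(map, ...) {
  pixel <- attr(map, "object_pixel") %||% 1
  df <- raster_tibble(map, pixel)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [µm]", y = "y [µm]",
                  fill = "summed\nintensity",
                  title = sprintf("trajectory map at z = %g µm",
                                  attr(map, "z") %||% NA))
}

#' Plot linked particle tracks
#'
#' @param tracks Tibble from [link_tracks()].
#' @param ... Unused.
#' @return A ggplot object (x-y projection, one colour per track).
#' @export
plot_tracks <- function(tracks, ...) {
  ggplot2::ggplot(tracks,
                  ggplot2::aes(.data$x_um, .data$y_um,
                               colour = factor(.data$track_id),
                               group = .data$track_id)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [µm]", y = "y [µm]", colour = "track")
}

#' Plot a crosscut profile
#'
#' @param profile Tibble from [crosscut()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_crosscut <- function(profile, ...) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$position_um, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position [µm]",
                  y = attr(profile, "view_kind") %||% "value")
}
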