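focus_score <- function(field, metric, border = 0.1) {
  I <- Mod(field$values)^2
  if (border > 0) {
    br <- floor(nrow(I) * border)
    bc <- floor(ncol(I) * border)
    I <- I[(br + 1):(nrow(I) - br), (bc + 1):(ncol(I) - bc), drop = FALSE]
  }
  switch(metric,
    peak = max(I) / mean(I),
    max_intensity = max(I),
    tenengrad = {
      gx <- I[, -1, drop = FALSE] - I[, -ncol(I), drop = FALSE]
      gy <- I[-1, , drop = FALSE] - I[-nrow(I), , drop = FALSE]
      sum(gx^2) + sum(gy^2)
    },
    stop("unknown focus metric: ", metric)
  )
}

#' Autofocus: find the reconstruction depth of best focus
#'
#' Scans reconstruction depth with a coarse grid, then repeatedly shrinks a
#' bracketed grid around the running best depth (ternary-style refinement;
#' each pass divides the step by 8) until the grid is no coarser than
#' `refine_to`. Grid refinement rather than pure golden-section search is
#' used because the focus curve of a contrast hologram carries fine
#' twin-image interference ripples on top of the broad focus peak; a
#' bracketed grid is robust to them and remains fully deterministic.
#'
#' The default metric, `"peak"`, is the ratio of the maximum to the mean
#' reconstructed intensity over the central window (a fraction `border` of
#' each edge is excluded, since the periodic fast transform can wrap
#' defocused fringe energy onto the window boundary). The normalisation
#' makes the metric invariant to the strong depth dependence of the
#' overall reconstruction scale, which raw peak intensity is not; raw
#' `"max_intensity"` and `"tenengrad"` (gradient energy, for extended
#' objects) remain available.
#'
#' @inheritParams kh_reconstruct_direct
#' @param z_min,z_max Search interval, µm, inside (0, d).
#' @param coarse_step Initial scan step, µm.
#' @param refine_to Final grid resolution, µm (default 0.001).
#' @param metric `"peak"`, `"max_intensity"` or `"tenengrad"`.
#' @param border Edge fraction excluded from the metric (default 0.1).
#' @return An object of class `holo_autofocus` with elements `z_best`,
#'   `score_best`, `curve` (tibble of all evaluated `(z_um, score)`),
#'   `metric`, `n_evaluations`. Supports [tidy()] and [glance()].
#' @examples
#' g <- optical_geometry(sensor_shape = c(64, 64))
#' h <- simulate_hologram(scene(scatterers(z = 400)), g, noise_std = 0)
#' ctr <- contrast_hologram(h, simulate_background(g))
#' af <- autofocus(ctr, 300, 500, coarse_step = 10, refine_to = 0.01)
#' af$z_best
#' @export
autofocus <- function(contrast, z_min, z_max, coarse_step,
                      refine_to = 0.001,
                      metric = c("peak", "max_intensity", "tenengrad"),
                      border = 0.1) {
  metric <- match.arg(metric)
  stopifnot(is_hologram(contrast))
  d <- contrast$geometry$distance
  if (!(0 < z_min && z_min < z_max && z_max < d)) {
    stop("require 0 < z_min < z_max < source_screen_distance")
  }
  if (all(contrast$pixels == 0)) stop("no focusable signal: hologram is all zero")
  if (coarse_step <= 0 || refine_to <= 0) stop("steps must be positive")

  evals_z <- numeric(0)
  evals_s <- numeric(0)
  eval_at <- function(zs) {
    zs <- zs[zs > 0 & zs < d]
    s <- vapply(zs, function(z) {
      focus_score(kh_reconstruct_fast(contrast, z), metric, border)
    }, numeric(1))
    evals_z <<- c(evals_z, zs)
    evals_s <<- c(evals_s, s)
    list(z = zs, s = s)
  }

  coarse <- eval_at(seq(z_min, z_max, by = coarse_step))
  z0 <- coarse$z[which.max(coarse$s)]
  step <- coarse_step
  while (step > refine_to) {
    step <- step / 8
    ref <- eval_at(pmin(pmax(z0 + step * (-8:8), z_min), z_max))
    z0 <- ref$z[which.max(ref$s)]
  }

  ord <- order(evals_z)
  curve <- tibble::tibble(z_um = evals_z[ord], score = evals_s[ord])
  curve <- curve[!duplicated(curve$z_um), ]
  structure(
    list(z_best = z0, score_best = max(evals_s), curve = curve,
         metric = metric, n_evaluations = length(evals_z)),
    class = "holo_autofocus"
  )
}

#' @export
print.holo_autofocus <- function(x, ...) {
  cat(sprintf("<autofocus: z_best = %.3f um (%s metric, %d evaluations)>\n",
              x$z_best, x$metric, x$n_evaluations))
  invisible(x)
}

#' @describeIn autofocus Tidy the sampled focus curve into a tibble.
#' @param x A `holo_autofocus` object.
#' @param ... Unused.
#' @export
tidy.holo_autofocus <- function(x, ...) x$curve

#' @describeIn autofocus One-row summary of the focus search.
#' @export
glance.holo_autofocus <- function(x, ...) {
  tibble::tibble(z_best_um = x$z_best, score_best = x$score_best,
                 metric = x$metric, n_evaluations = x$n_evaluations)
}
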