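# Migration track metrics, protrusion orientation, corrected total cell
# fluorescence, oscillation-period estimation and kymograph extraction.

#' Chemotaxis metrics per track
#'
#' For each track: the travelled (accumulated) path length, the Euclidean
#' end-to-end distance, the mean velocity (travelled distance over elapsed
#' time), the directionality (Euclidean / travelled, a persistence measure in
#' `[0, 1]`), and the forward migration index (FMI), the net displacement
#' along the gradient axis divided by the travelled path length (the
#' chemotaxis-tool convention; set `fmi_denominator = "euclidean"` for the
#' variant normalized by end-to-end distance).
#'
#' @param tracks Tibble with columns `track_id`, `t_min`, `x`, `y` (times
#'   strictly increasing within a track; at least 2 samples).
#' @param axis Gradient direction `(gx, gy)`; normalized internally.
#' @param fmi_denominator `"travelled"` (default) or `"euclidean"`.
#'
#' @return A tibble with one row per track: `track_id`, `n_samples`,
#'   `duration_min`, `travelled`, `euclidean`, `velocity`, `directionality`,
#'   `fmi`.
#' @export
track_metrics <- function(tracks, axis = c(1, 0),
                          fmi_denominator = c("travelled", "euclidean")) {
  fmi_denominator <- match.arg(fmi_denominator)
  needed <- c("track_id", "t_min", "x", "y")
  if (!all(needed %in% names(tracks))) {
    abort("`tracks` must have columns track_id, t_min, x, y.")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) abort("`axis` must be a non-zero vector.")
  axis <- axis / nrm
  one <- function(d) {
    d <- d[order(d$t_min), ]
    if (nrow(d) < 2) abort("Each track needs at least 2 samples.")
    if (any(diff(d$t_min) <= 0)) {
      abort("Track timestamps must be strictly increasing (no duplicates).")
    }
    dx <- diff(d$x); dy <- diff(d$y)
    steps <- sqrt(dx^2 + dy^2)
    travelled <- sum(steps)
    disp <- c(d$x[nrow(d)] - d$x[1], d$y[nrow(d)] - d$y[1])
    euclid <- sqrt(sum(disp^2))
    dur <- d$t_min[nrow(d)] - d$t_min[1]
    denom <- if (fmi_denominator == "travelled") travelled else euclid
    tibble::tibble(
      n_samples = nrow(d), duration_min = dur, travelled = travelled,
      euclidean = euclid, velocity = travelled / dur,
      directionality = if (travelled > 0) euclid / travelled else 0,
      fmi = if (denom > 0) sum(disp * axis) / denom else 0
    )
  }
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Protrusion orientation angle relative to the gradient
#'
#' The angle between a protrusion extension vector and the chemoattractant
#' gradient axis, in degrees: 0 means aligned with the gradient, 90
#' perpendicular, 180 anti-parallel. With `fold = TRUE` angles are folded to
#' `[0, 90]` via `min(angle, 180 - angle)`, reporting alignment with the
#' gradient axis regardless of sign.
#'
#' @param dx,dy Protrusion vector components (vectorized).
#' @param axis Gradient direction `(gx, gy)`.
#' @param fold Fold angles to `[0, 90]`?
#'
#' @return Angles in degrees.
#' @export
protrusion_angle <- function(dx, dy, axis = c(1, 0), fold = FALSE) {
  nrm <- sqrt(dx^2 + dy^2)
  if (any(nrm == 0)) abort("Protrusion vectors must be non-zero.")
  anrm <- sqrt(sum(axis^2))
  if (anrm == 0) abort("`axis` must be a non-zero vector.")
  ct <- (dx * axis[1] + dy * axis[2]) / (nrm * anrm)
  ang <- acos(clamp(ct, -1, 1)) * 180 / pi
  if (fold) pmin(ang, 180 - ang) else ang
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated density - (cell area x mean background fluorescence)`,
#' the standard background-corrected per-cell fluorescence used to quantify
#' dextran uptake (macropinocytosis). Negative values are reported as-is.
#'
#' @param integrated_density Integrated density of the cell ROI (A.U.).
#' @param cell_area Area of the cell ROI in pixels (> 0).
#' @param background_mean Mean fluorescence of the background readings
#'   (A.U. per pixel).
#'
#' @return CTCF in arbitrary units. Vectorized.
#' @export
ctcf <- function(integrated_density, cell_area, background_mean) {
  if (any(cell_area <= 0)) abort("`cell_area` must be positive.")
  integrated_density - cell_area * background_mean
}

# Centred moving average with replicated ends (window forced odd).
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(padded, rep(1 / window, window),
                           sides = 2))[(half + 1L):(half + length(x))]
}

# Local maxima with topographic prominence.
find_peaks <- function(x, min_prominence, min_separation) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- if (any(x[seq_len(i - 1)] > x[i])) {
      j <- max(which(x[seq_len(i - 1)] > x[i]))
      min(x[j:i])
    } else min(x[1:i])
    right <- if (any(x[(i + 1):n] > x[i])) {
      j <- i + min(which(x[(i + 1):n] > x[i]))
      min(x[i:j])
    } else min(x[i:n])
    x[i] - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  ord <- order(-promk, keep)
  chosen <- integer(0)
  for (i in ord) {
    if (!length(chosen) || all(abs(keep[i] - chosen) >= min_separation)) {
      chosen <- c(chosen, keep[i])
    }
  }
  sort(chosen)
}

#' Oscillation period of an intensity trace
#'
#' Detects recurrent peaks (local maxima with topographic prominence at least
#' `prominence_frac` of the trace's dynamic range, separated by at least
#' `min_separation` samples) and returns the mean inter-peak interval in
#' minutes. The relative prominence criterion makes the estimate invariant to
#' affine rescaling of the intensities.
#'
#' @param trace Numeric intensity vector, or a tibble with an `intensity`
#'   column (as from [generate_oscillation_trace()]).
#' @param dt Sampling interval in seconds.
#' @param prominence_frac Minimum peak prominence as a fraction of
#'   `max(trace) - min(trace)`.
#' @param min_separation Minimum peak separation in samples.
#' @param smooth_window Width (samples) of the centred moving average applied
#'   before peak detection; suppresses single-sample noise maxima without
#'   shifting the peaks of a symmetric pulse. Set to 1 to disable.
#'
#' @return The period in minutes, or `NA_real_` (with a warning) when fewer
#'   than two peaks are detectable.
#' @export
oscillation_period <- function(trace, dt, prominence_frac = 0.25,
                               min_separation = 4, smooth_window = 3) {
  if (is.data.frame(trace)) trace <- trace$intensity
  if (!is.numeric(trace) || length(trace) < 3) {
    abort("`trace` must be a numeric series of length >= 3.")
  }
  trace <- moving_average(trace, smooth_window)
  rng <- max(trace) - min(trace)
  if (rng == 0) {
    warn("Constant trace: no peaks, period undefined.")
    return(NA_real_)
  }
  peaks <- find_peaks(trace, min_prominence = prominence_frac * rng,
                      min_separation = min_separation)
  if (length(peaks) < 2) {
    warn("Fewer than two peaks detected: period undefined.")
    return(NA_real_)
  }
  mean(diff(peaks)) * dt / 60
}

#' Kymograph along a line ROI
#'
#' Samples the intensity along a fixed line segment in every frame by
#' bilinear interpolation at 1-pixel steps, producing a position-by-time
#' image. A front moving at constant speed appears as a ridge whose slope is
#' the speed in pixels per frame.
#'
#' @param stack List of frame matrices (time-ordered), all the same shape.
#' @param roi_line Numeric `c(x0, y0, x1, y1)` in 0-based pixel coordinates
#'   (`x` = column, `y` = row); both endpoints must lie inside the image.
#'
#' @return A numeric matrix, positions along the ROI in rows, frames in
#'   columns.
#' @export
cdr_edge_kymograph <- function(stack, roi_line) {
  if (!length(stack)) abort("`stack` must contain at least one frame.")
  if (length(roi_line) != 4) abort("`roi_line` must be c(x0, y0, x1, y1).")
  h <- nrow(stack[[1]]); w <- ncol(stack[[1]])
  xs <- roi_line[c(1, 3)]; ys <- roi_line[c(2, 4)]
  if (any(xs < 0 | xs > w - 1 | ys < 0 | ys > h - 1)) {
    abort("ROI endpoints must lie inside the image bounds.")
  }
  len <- sqrt(diff(xs)^2 + diff(ys)^2)
  n_pos <- max(2L, floor(len) + 1L)
  tt <- seq(0, 1, length.out = n_pos)
  px <- xs[1] + tt * diff(xs)
  py <- ys[1] + tt * diff(ys)
  interp <- function(img) {
    x0 <- clamp(floor(px), 0, w - 1); y0 <- clamp(floor(py), 0, h - 1)
    x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
    fx <- px - x0; fy <- py - y0
    v00 <- img[cbind(y0 + 1, x0 + 1)]; v01 <- img[cbind(y0 + 1, x1 + 1)]
    v10 <- img[cbind(y1 + 1, x0 + 1)]; v11 <- img[cbind(y1 + 1, x1 + 1)]
    (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  }
  ky <- vapply(stack, function(fr) {
    assert_same_dim(fr, stack[[1]], "kymograph frames")
    interp(fr)
  }, numeric(n_pos))
  matrix(ky, nrow = n_pos)
}
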