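# ggplot2 views of the screen's results and of kinematics data.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ranked CDR scores of a screen
#'
#' Point plot of per-siRNA CDR scores ranked ascending, with the hit
#' threshold drawn as a dashed line; the screen's standard ranking view.
#'
#' @param object A `cdr_screen` result.
#' @param threshold Hit threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cdr_screen
#' @export
autoplot.cdr_screen <- function(object, threshold = 0.4, ...) {
  roles <- object$images |>
    dplyr::distinct(.data$treatment_id, .data$role)
  d <- object$treatments |>
    dplyr::filter(!.data$inconclusive) |>
    dplyr::left_join(roles, by = "treatment_id") |>
    dplyr::arrange(.data$cdr_score) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$cdr_score,
                                  colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "siRNA rank", y = "CDR score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Spider plot of migration tracks
#'
#' All tracks are translated to a common origin; the gradient axis points
#' right by convention.
#'
#' @param tracks Tracks tibble (`track_id`, `t_min`, `x`, `y`).
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks) {
  d <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$t_min, .by_group = TRUE) |>
    dplyr::mutate(x = .data$x - dplyr::first(.data$x),
                  y = .data$y - dplyr::first(.data$y)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  group = .data$track_id)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (re-zeroed)", y = "y (re-zeroed)") +
    ggplot2::theme_minimal()
}

#' Intensity trace with detected oscillation peaks
#'
#' @param trace Tibble from [generate_oscillation_trace()] (columns `t_s`,
#'   `intensity`) or a numeric vector with `dt` given.
#' @param dt Sampling interval in seconds (required for numeric input).
#' @param prominence_frac,min_separation,smooth_window Passed to the peak
#'   detector (see [oscillation_period()]).
#' @return A ggplot.
#' @export
plot_trace <- function(trace, dt = NULL, prominence_frac = 0.25,
                       min_separation = 4, smooth_window = 3) {
  if (is.data.frame(trace)) {
    t_s <- trace$t_s
    x <- trace$intensity
  } else {
    if (is.null(dt)) abort("`dt` is required for a bare numeric trace.")
    x <- trace
    t_s <- (seq_along(x) - 1) * dt
  }
  xs <- moving_average(x, smooth_window)
  rng <- max(xs) - min(xs)
  pk <- if (rng > 0) {
    find_peaks(xs, prominence_frac * rng, min_separation)
  } else integer(0)
  d <- tibble::tibble(t_min = t_s / 60, intensity = x)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$t_min, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "intensity (A.U.)") +
    ggplot2::theme_minimal()
  if (length(pk)) {
    p <- p + ggplot2::geom_point(data = d[pk, ], colour = "red")
  }
  p
}

#' Display one synthetic field
#'
#' Raster view of a chosen channel, optionally with ground-truth CDR pixels
#' outlined.
#'
#' @param field One row of a [generate_plate()] tibble (or the list returned
#'   by [render_image_set()]).
#' @param channel `"actin"`, `"membrane"` or `"nucleus"`.
#' @param show_cdr Overlay ground-truth CDR pixels?
#' @return A ggplot.
#' @export
plot_field <- function(field, channel = "actin", show_cdr = FALSE) {
  if (is.data.frame(field)) {
    img <- field$images[[1]][[channel]]
    truth <- field$truth[[1]]
  } else {
    img <- field$images[[channel]]
    truth <- field$truth
  }
  d <- tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    value = as.numeric(img)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = channel) +
    ggplot2::theme_void()
  if (show_cdr && !is.null(truth) && any(truth$cdr_mask)) {
    idx <- which(truth$cdr_mask, arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(col = idx[, 2], row = idx[, 1]),
      mapping = ggplot2::aes(.data$col, .data$row),
      inherit.aes = FALSE, colour = "red", size = 0.1, alpha = 0.3)
  }
  p
}
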