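# Synthetic cell tracks and intensity traces for the kinematics module.

#' Generate biased-random-walk cell tracks
#'
#' Each track takes steps of exact length `speed * dt` whose direction is the
#' normalized mixture `bias * axis + (1 - bias) * u`, with `u` uniform on the
#' unit circle. `gradient_bias = 1` gives straight-line motion along the
#' gradient axis; `gradient_bias = 0` gives an unbiased random walk.
#'
#' @param n_tracks Number of tracks.
#' @param n_steps Number of samples per track (>= 2); positions are recorded
#'   at times `0, dt, ..., (n_steps - 1) * dt` minutes.
#' @param dt Sampling interval in minutes.
#' @param speed Step speed in length units per minute (>= 0).
#' @param gradient_bias Drift fraction in `[0, 1]`.
#' @param rng_seed Integer seed.
#' @param axis Unit vector of the gradient direction `(gx, gy)`.
#'
#' @return A tibble: `track_id`, `t_min`, `x`, `y`.
#' @export
generate_tracks <- function(n_tracks, n_steps, dt = 5, speed = 1,
                            gradient_bias = 0, rng_seed = 1, axis = c(1, 0)) {
  if (n_steps < 2) abort("`n_steps` must be at least 2.")
  if (speed < 0) abort("`speed` must be non-negative.")
  if (gradient_bias < 0 || gradient_bias > 1) {
    abort("`gradient_bias` must lie in [0, 1].")
  }
  axis <- axis / sqrt(sum(axis^2))
  step_len <- speed * dt
  with_seed(rng_seed, {
    tracks <- purrr::map(seq_len(n_tracks), function(id) {
      pos <- matrix(0, n_steps, 2)
      pos[1, ] <- runif(2, 0, 100)
      for (i in 2:n_steps) {
        repeat {
          a <- runif(1, 0, 2 * pi)
          d <- gradient_bias * axis + (1 - gradient_bias) * c(cos(a), sin(a))
          nd <- sqrt(sum(d^2))
          if (nd > 1e-9) break
        }
        pos[i, ] <- pos[i - 1, ] + step_len * d / nd
      }
      tibble::tibble(track_id = id, t_min = (seq_len(n_steps) - 1) * dt,
                     x = pos[, 1], y = pos[, 2])
    })
    dplyr::bind_rows(tracks)
  })
}

#' Generate a noisy oscillatory intensity trace
#'
#' Emulates the fluorescence intensity of a region where CDRs form
#' recurrently: peaks repeat at the given period on top of noise. The trace
#' is `0.5 * (1 - cos(2*pi*t/period))` (range 0..1, peaks every period,
#' first peak at half a period) for `shape = "sine"`, or a train of Gaussian
#' pulses at the same times for `shape = "pulse"`.
#'
#' @param period Oscillation period in minutes.
#' @param dt Sampling interval in seconds; must respect the Nyquist margin
#'   `dt < period * 60 / 4`.
#' @param duration Trace duration in minutes; must cover at least 2 periods.
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   unit peak amplitude.
#' @param rng_seed Integer seed.
#' @param shape `"sine"` or `"pulse"`.
#'
#' @return A tibble: `t_s` (seconds), `intensity`.
#' @export
generate_oscillation_trace <- function(period, dt, duration, noise_sd = 0,
                                       rng_seed = 1,
                                       shape = c("sine", "pulse")) {
  shape <- match.arg(shape)
  if (dt >= period * 60 / 4) {
    abort("`dt` must be smaller than a quarter period (Nyquist margin).")
  }
  if (duration < 2 * period) {
    abort("`duration` must cover at least two periods.")
  }
  t_s <- seq(0, duration * 60, by = dt)
  p_s <- period * 60
  base <- if (shape == "sine") {
    0.5 * (1 - cos(2 * pi * t_s / p_s))
  } else {
    peaks <- seq(p_s / 2, max(t_s), by = p_s)
    rowSums(vapply(peaks, function(pk) exp(-(t_s - pk)^2 / (2 * (p_s / 10)^2)),
                   numeric(length(t_s))))
  }
  intensity <- if (noise_sd > 0) {
    with_seed(rng_seed, base + rnorm(length(base), 0, noise_sd))
  } else {
    base
  }
  tibble::tibble(t_s = t_s, intensity = intensity)
}
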