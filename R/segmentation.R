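#' Robust background threshold
#'
#' Global intensity threshold from trimmed background statistics: the dimmest
#' and brightest fractions of pixels are discarded as outliers and the
#' threshold is the mean plus `n_sd` standard deviations of the remaining
#' population, clipped to the valid grey range. With the default trims this is
#' the conventional robust-background rule used by high-content pipelines for
#' thresholding sparse primary objects such as nuclei; for images where the
#' foreground covers a large area fraction, raise `upper_trim` so that
#' foreground pixels are excluded from the background estimate.
#'
#' @param image Numeric matrix of grey values.
#' @param lower_trim,upper_trim Fractions of the dimmest / brightest pixels to
#'   discard before computing the statistics.
#' @param n_sd Number of standard deviations above the trimmed mean.
#' @param max_value Upper clip for the returned threshold (12-bit default).
#'
#' @return A single grey-value threshold.
#' @export
robust_background_threshold <- function(image, lower_trim = 0.05,
                                        upper_trim = 0.05, n_sd = 2,
                                        max_value = 4095) {
  assert_image(image)
  if (lower_trim < 0 || upper_trim < 0 || lower_trim + upper_trim >= 1) {
    abort("Trim fractions must be non-negative and sum to less than 1.")
  }
  v <- sort(as.numeric(image))
  n <- length(v)
  lo <- floor(n * lower_trim)
  hi <- floor(n * upper_trim)
  v <- v[(lo + 1L):(n - hi)]
  s <- if (length(v) > 1L) sd(v) else 0
  clamp(mean(v) + n_sd * s, 0, max_value)
}

#' Segment nuclei from the DNA-stain channel
#'
#' Thresholds the nucleus image with [robust_background_threshold()], fills
#' holes, labels 8-connected components and removes components smaller than
#' `min_size` pixels. Nuclei are the seeds for cell segmentation.
#'
#' @param nucleus Numeric matrix (DNA-stain channel).
#' @param min_size Minimum nucleus area in pixels.
#' @param lower_trim,upper_trim,n_sd Passed to [robust_background_threshold()].
#'
#' @return An integer label matrix with labels `1..N` (0 = background).
#' @export
segment_nuclei <- function(nucleus, min_size = 50, lower_trim = 0.05,
                           upper_trim = 0.05, n_sd = 2) {
  assert_image(nucleus, "nucleus")
  thr <- robust_background_threshold(nucleus, lower_trim, upper_trim, n_sd)
  mask <- nucleus > thr
  if (!any(mask)) return(matrix(0L, nrow(nucleus), ncol(nucleus)))
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  mask <- matrix(as.numeric(filled) > 0, nrow(nucleus), ncol(nucleus))
  lab <- label_components_cpp(mask, eight = TRUE)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) return(matrix(0L, nrow(nucleus), ncol(nucleus)))
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  out
}

#' Focus quality: slope of the log-log radial power spectrum
#'
#' Computes the radially averaged power spectral density of the image and fits
#' a least-squares line to `log10(power)` versus `log10(frequency)` over the
#' frequency band `band` (cycles/pixel). Blurring removes high-frequency
#' power, so blurrier images give more negative slopes; the screen's quality
#' control rejects images whose nucleus-channel slope falls below -2. The
#' statistic is invariant to additive offsets (the DC term is excluded) and to
#' multiplicative rescaling (which shifts the log-spectrum without changing
#' its slope).
#'
#' @param image Numeric matrix, at least 32x32.
#' @param band Frequency band (cycles/pixel) used for the fit; excludes DC and
#'   the noise-dominated corner above 0.45.
#'
#' @return The fitted slope (dimensionless), or `NA_real_` for a constant
#'   image (zero power at all non-DC frequencies), with a warning.
#' @export
power_log_log_slope <- function(image, band = c(0.05, 0.45)) {
  assert_image(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 32 || w < 32) abort("`image` must be at least 32x32 pixels.")
  x <- image - mean(image)
  if (all(x == 0)) {
    warn("Constant image: focus slope is undefined.")
    return(NA_real_)
  }
  P <- Mod(fft(x))^2 / length(x)
  fy <- pmin(0:(h - 1), h - (0:(h - 1))) / h
  fx <- pmin(0:(w - 1), w - (0:(w - 1))) / w
  FR <- sqrt(outer(fy^2, fx^2, `+`))
  # unit-width annuli in frequency-index space of the smaller dimension
  step <- 1 / min(h, w)
  bin <- round(FR / step)
  keep <- bin > 0
  pow <- tapply(P[keep], bin[keep], mean)
  freq <- as.numeric(names(pow)) * step
  sel <- freq >= band[1] & freq <= band[2] & pow > 0
  if (sum(sel) < 3) {
    warn("Too few spectral bins with power in the fitting band.")
    return(NA_real_)
  }
  unname(coef(lm(log10(pow[sel]) ~ log10(freq[sel])))[2])
}

#' Segment cells by seeded watershed on the membrane channel
#'
#' The membrane image is background-corrected (subtraction of a coarse
#' Gaussian background estimate) and smoothed, then cells are grown from the
#' nucleus seeds by watershed flooding of the inverted corrected image,
#' restricted to a foreground mask obtained with
#' [robust_background_threshold()] of the corrected image. Because adherent
#' cells cover a large fraction of the field, the mask threshold uses a higher
#' upper trim (`mask_upper_trim`) than the nucleus default, so that the
#' background statistics are estimated from background pixels only. Each cell
#' inherits the label of its seed nucleus; a nucleus with no surrounding
#' membrane foreground yields a cell equal to its own footprint.
#'
#' @param nuclei Integer label matrix of nucleus seeds (see
#'   [segment_nuclei()]).
#' @param membrane Numeric matrix (membrane channel).
#' @param bg_sigma Gaussian sigma (px) of the coarse background estimate.
#' @param smooth_sigma Gaussian sigma (px) of the pre-watershed smoothing.
#' @param mask_upper_trim Upper trim fraction for the foreground-mask
#'   threshold.
#' @param mask_n_sd Standard-deviation multiplier for the mask threshold.
#'
#' @return Integer label matrix of cells; labels match the seed nuclei.
#' @export
segment_cells <- function(nuclei, membrane, bg_sigma = 50, smooth_sigma = 2,
                          mask_upper_trim = 0.35, mask_n_sd = 2) {
  assert_image(membrane, "membrane")
  assert_same_dim(nuclei, membrane, "`nuclei` and `membrane`")
  if (max(nuclei) == 0L) return(matrix(0L, nrow(membrane), ncol(membrane)))
  corrected <- membrane - gauss_smooth(membrane, bg_sigma)
  smoothed <- gauss_smooth(corrected, smooth_sigma)
  thr <- robust_background_threshold(smoothed, lower_trim = 0.05,
                                     upper_trim = mask_upper_trim,
                                     n_sd = mask_n_sd)
  mask <- smoothed > thr | nuclei > 0L
  storage.mode(nuclei) <- "integer"
  watershed_seeded_cpp(-smoothed, nuclei, mask)
}

#' Shrink cell objects by per-object erosion
#'
#' Each labelled object is eroded independently by a Euclidean disk of radius
#' `n_px` (pixels whose distance to the object's complement exceeds `n_px`).
#' This excludes cell-boundary pixels, which are prone to misclassification as
#' CDR, before any per-cell measurement. Objects whose erosion is empty are
#' dropped; surviving objects keep their original labels.
#'
#' @param cells Integer label matrix.
#' @param n_px Erosion radius in pixels (0 = identity).
#'
#' @return Integer label matrix of shrunk objects.
#' @export
shrink_cells <- function(cells, n_px = 5) {
  if (!is.matrix(cells)) abort("`cells` must be an integer label matrix.")
  if (n_px < 0) abort("`n_px` must be non-negative.")
  if (n_px == 0) return(cells)
  h <- nrow(cells); w <- ncol(cells)
  out <- matrix(0L, h, w)
  labs <- sort(unique(cells[cells > 0L]))
  pad <- as.integer(ceiling(n_px) + 1L)
  for (lb in labs) {
    idx <- which(cells == lb, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(h, max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(w, max(idx[, 2]) + pad)
    crop <- matrix(0, r1 - r0 + 1L + 2L * pad, c1 - c0 + 1L + 2L * pad)
    crop[cbind(idx[, 1] - r0 + 1L + pad, idx[, 2] - c0 + 1L + pad)] <- 1
    d <- EBImage::distmap(EBImage::Image(crop))
    keepm <- matrix(as.numeric(d) > n_px, nrow(crop), ncol(crop))
    ki <- which(keepm, arr.ind = TRUE)
    if (nrow(ki) == 0L) next
    out[cbind(ki[, 1] + r0 - 1L - pad, ki[, 2] + c0 - 1L - pad)] <- lb
  }
  out
}

#' Measure and filter cells on the actin channel
#'
#' Measures each (shrunk) cell object on the raw actin image and applies the
#' screen's cell filters: cells are kept only if their area is at least
#' `min_area` pixels, their mean actin grey value is at least `min_mean`, and
#' they contain at most `max_saturated` saturated pixels (grey value equal to
#' `saturation_value`). Rejection conditions are strict as printed (area
#' "less than 2500", mean "less than 200", "more than 500" saturated pixels);
#' equality keeps the cell. `reject_reason` reports the first failed rule in
#' the order size, dim, saturated.
#'
#' @param cells Integer label matrix of (shrunk) cell objects.
#' @param actin Numeric matrix, raw actin channel.
#' @param min_area Minimum object area in pixels.
#' @param min_mean Minimum mean actin grey value.
#' @param max_saturated Maximum allowed count of saturated actin pixels.
#' @param saturation_value Grey value counted as saturated.
#'
#' @return A tibble with one row per cell object: `label`, `area_px`,
#'   `mean_actin`, `saturated_px`, `kept`, `reject_reason`.
#' @export
filter_cells <- function(cells, actin, min_area = 2500, min_mean = 200,
                         max_saturated = 500, saturation_value = 4095) {
  assert_image(actin, "actin")
  assert_same_dim(cells, actin, "`cells` and `actin`")
  nz <- cells > 0L
  if (!any(nz)) {
    return(tibble::tibble(label = integer(), area_px = integer(),
                          mean_actin = numeric(), saturated_px = integer(),
                          kept = logical(), reject_reason = character()))
  }
  lab <- cells[nz]
  val <- actin[nz]
  area <- tapply(val, lab, length)
  mean_actin <- tapply(val, lab, mean)
  sat <- tapply(val == saturation_value, lab, sum)
  labels <- as.integer(names(area))
  reason <- rep("none", length(labels))
  reason[as.numeric(sat) > max_saturated] <- "too_saturated"
  reason[as.numeric(mean_actin) < min_mean] <- "too_dim"
  reason[as.numeric(area) < min_area] <- "too_small"
  tibble::tibble(
    label = labels,
    area_px = as.integer(area),
    mean_actin = as.numeric(mean_actin),
    saturated_px = as.integer(sat),
    kept = reason == "none",
    reject_reason = reason
  )
}
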