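# Per-image scoring, image QC, per-plate normalization against the negative
# control, per-siRNA aggregation and gene-level hit calling.

#' Score one image from its kept cells
#'
#' The per-image raw score is the mean CDR pixel count over the kept cells of
#' the image. Quality control rejects images that are out of focus (focus
#' slope below `min_focus_slope`, or undefined) or contain too few kept cells
#' (fewer than `min_cells`); rejection boundaries are strict, so a slope of
#' exactly -2 or a cell count of exactly 20 passes. An image with zero kept
#' cells has an undefined (NA) raw score and fails QC; it is never averaged.
#'
#' @param cells Cell-record tibble from [filter_cells()].
#' @param per_cell_pixels Named integer vector of CDR pixel counts per kept
#'   cell (see [count_cdr_pixels_per_cell()]).
#' @param focus_slope Focus-quality slope of the nucleus channel (see
#'   [power_log_log_slope()]).
#' @param min_cells Minimum number of kept cells.
#' @param min_focus_slope Minimum focus slope.
#'
#' @return A one-row tibble: `count_cells`, `focus_slope`, `raw_score`,
#'   `qc_pass`, `qc_reason`.
#' @export
score_image <- function(cells, per_cell_pixels, focus_slope,
                        min_cells = 20, min_focus_slope = -2) {
  kept <- cells$label[cells$kept]
  count <- length(kept)
  raw <- NA_real_
  if (count > 0) {
    key <- as.character(kept)
    missing <- setdiff(key, names(per_cell_pixels))
    if (length(missing)) {
      abort("`per_cell_pixels` lacks counts for some kept cells.")
    }
    raw <- mean(per_cell_pixels[key])
  }
  if (is.na(focus_slope) || focus_slope < min_focus_slope) {
    reason <- "out_of_focus"
  } else if (count < min_cells) {
    reason <- "too_few_cells"
  } else {
    reason <- "pass"
  }
  tibble::tibble(count_cells = count, focus_slope = focus_slope,
                 raw_score = raw, qc_pass = reason == "pass",
                 qc_reason = reason)
}

#' Normalize per-image raw scores against the plate's negative control
#'
#' For each plate, every QC-passing image's raw score is divided by the mean
#' raw score of the QC-passing negative-control images of the same plate,
#' yielding the ratio score. Plates without any passing negative-control
#' image cannot be normalized; their images are dropped with a warning.
#'
#' @param images Per-image tibble with at least `plate`, `treatment_id`,
#'   `raw_score`, `qc_pass` columns.
#' @param negative_control_id Treatment id of the negative-control siRNA.
#'
#' @return The input with a `ratio_score` column (NA for QC-failing images),
#'   minus any plate that could not be normalized.
#' @export
normalize_plate <- function(images, negative_control_id) {
  needed <- c("plate", "treatment_id", "raw_score", "qc_pass")
  if (!all(needed %in% names(images))) {
    abort(paste0("`images` must contain columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (!any(images$treatment_id == negative_control_id)) {
    abort(sprintf("No images with negative control treatment '%s'.",
                  negative_control_id))
  }
  ctrl <- images |>
    dplyr::filter(.data$qc_pass, .data$treatment_id == negative_control_id) |>
    dplyr::group_by(.data$plate) |>
    dplyr::summarise(ctrl_mean = mean(.data$raw_score), .groups = "drop")
  bad <- setdiff(unique(images$plate), ctrl$plate)
  bad <- union(bad, ctrl$plate[!is.finite(ctrl$ctrl_mean) | ctrl$ctrl_mean <= 0])
  if (length(bad)) {
    warn(paste0("Excluding plate(s) without usable QC-passing negative-control",
                " images: ", paste(bad, collapse = ", ")))
  }
  images |>
    dplyr::filter(!.data$plate %in% bad) |>
    dplyr::left_join(ctrl, by = "plate") |>
    dplyr::mutate(ratio_score = ifelse(.data$qc_pass,
                                       .data$raw_score / .data$ctrl_mean,
                                       NA_real_)) |>
    dplyr::select(-"ctrl_mean")
}

#' Aggregate ratio scores into per-siRNA CDR scores
#'
#' For each siRNA, the CDR score is the mean ratio score over all QC-passing
#' images across replicate plates (per-image pooling; set
#' `pooling = "per_plate"` to average plate means instead). Treatments with no
#' QC-passing image are flagged inconclusive (cytotoxic or out-of-focus wells)
#' and carry no score.
#'
#' @param images Normalized per-image tibble (see [normalize_plate()]) with
#'   `treatment_id`, `gene`, `qc_pass`, `ratio_score` (and `plate` for
#'   per-plate pooling).
#' @param hit_threshold CDR score below which a siRNA is a hit (strict).
#' @param pooling `"per_image"` (default) or `"per_plate"`.
#'
#' @return A tibble with one row per siRNA: `treatment_id`, `gene`,
#'   `cdr_score`, `n_images`, `inconclusive`, `is_hit`.
#' @export
aggregate_treatments <- function(images, hit_threshold = 0.4,
                                 pooling = c("per_image", "per_plate")) {
  pooling <- match.arg(pooling)
  if (!"ratio_score" %in% names(images)) {
    abort("`images` has no ratio_score; run normalize_plate() first.")
  }
  passing <- dplyr::filter(images, .data$qc_pass, !is.na(.data$ratio_score))
  scored <- if (pooling == "per_image") {
    passing |>
      dplyr::group_by(.data$treatment_id, .data$gene) |>
      dplyr::summarise(cdr_score = mean(.data$ratio_score),
                       n_images = dplyr::n(), .groups = "drop")
  } else {
    passing |>
      dplyr::group_by(.data$treatment_id, .data$gene, .data$plate) |>
      dplyr::summarise(plate_mean = mean(.data$ratio_score),
                       n_images = dplyr::n(), .groups = "drop") |>
      dplyr::group_by(.data$treatment_id, .data$gene) |>
      dplyr::summarise(cdr_score = mean(.data$plate_mean),
                       n_images = sum(.data$n_images), .groups = "drop")
  }
  all_treat <- dplyr::distinct(images, .data$treatment_id, .data$gene)
  all_treat |>
    dplyr::left_join(scored, by = c("treatment_id", "gene")) |>
    dplyr::mutate(
      n_images = ifelse(is.na(.data$n_images), 0L, .data$n_images),
      inconclusive = .data$n_images == 0L,
      is_hit = !.data$inconclusive & .data$cdr_score < hit_threshold
    )
}

#' Gene-level hit validation
#'
#' A siRNA is a hit when its CDR score is strictly below `threshold`
#' (equivalently, more than a 60% reduction relative to the negative control
#' at the default 0.4). A gene is validated when at least `min_sirnas` of its
#' conclusive siRNAs are hits. Genes whose siRNAs are all inconclusive are
#' reported as inconclusive. The output is ranked by gene-level mean CDR
#' score, ascending.
#'
#' @param scores Per-siRNA tibble from [aggregate_treatments()].
#' @param threshold Hit threshold on the CDR score (strict `<`).
#' @param min_sirnas Minimum number of hit siRNAs for validation.
#' @param sirnas_per_gene Expected library size per gene (recorded; a warning
#'   is emitted if a gene exceeds it).
#'
#' @return A tibble with one row per gene: `gene`, `n_sirnas`,
#'   `n_conclusive`, `n_hits`, `mean_cdr_score`, `validated`, `inconclusive`.
#' @export
call_hits <- function(scores, threshold = 0.4, min_sirnas = 2,
                      sirnas_per_gene = 3) {
  out <- scores |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_sirnas = dplyr::n(),
      n_conclusive = sum(!.data$inconclusive),
      n_hits = sum(!.data$inconclusive & .data$cdr_score < threshold),
      mean_cdr_score = if (any(!.data$inconclusive)) {
        mean(.data$cdr_score[!.data$inconclusive])
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      inconclusive = .data$n_conclusive == 0L,
      validated = !.data$inconclusive & .data$n_hits >= min_sirnas
    ) |>
    dplyr::arrange(.data$mean_cdr_score)
  if (any(out$n_sirnas > sirnas_per_gene)) {
    warn("Some genes have more siRNAs than `sirnas_per_gene`.")
  }
  out
}

#' Manual CDR score (fraction of CDR-positive cells, control-normalized)
#'
#' The manually counted variant of the screen's readout: the fraction of
#' CDR-positive cells in a condition divided by the fraction in the control
#' condition.
#'
#' @param n_positive Number of CDR-positive cells counted.
#' @param n_total Total number of cells counted (> 0).
#' @param control_fraction CDR-positive fraction of the control condition
#'   (> 0).
#'
#' @return The normalized score (1 = control-like). Vectorized.
#' @export
manual_cdr_score <- function(n_positive, n_total, control_fraction) {
  if (any(n_total <= 0)) abort("`n_total` must be positive.")
  if (any(control_fraction <= 0)) abort("`control_fraction` must be positive.")
  (n_positive / n_total) / control_fraction
}
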