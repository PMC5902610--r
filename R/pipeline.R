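# End-to-end screen pipeline: channels -> segmentation -> CDR detection ->
# per-image score row.

#' Process one field of view through the full pipeline
#'
#' Runs nucleus segmentation, focus QC, seeded-watershed cell segmentation,
#' cell shrinking and filtering, pixel classification, CDR post-processing
#' and per-cell counting for a single three-channel field.
#'
#' @param images List with `actin`, `membrane`, `nucleus` matrices.
#' @param clf A trained [train_pixel_classifier()].
#' @param shrink_px Cell shrink radius in pixels.
#' @param threshold,closing_diameter,min_area Passed to [segment_cdrs()].
#' @param min_cells,min_focus_slope Passed to [score_image()].
#'
#' @return A list: `score` (one-row tibble), `cells` (cell records),
#'   `per_cell_pixels`, `cell_labels`, `kept_cells`, `cdr` (the
#'   `cdr_objects`).
#' @export
process_field <- function(images, clf, shrink_px = 5, threshold = 0.51,
                          closing_diameter = 7, min_area = 25,
                          min_cells = 20, min_focus_slope = -2) {
  nuclei <- segment_nuclei(images$nucleus)
  slope <- suppressWarnings(power_log_log_slope(images$nucleus))
  cells <- segment_cells(nuclei, images$membrane)
  shrunk <- shrink_cells(cells, n_px = shrink_px)
  records <- filter_cells(shrunk, images$actin)
  kept <- shrunk
  drop <- records$label[!records$kept]
  if (length(drop)) kept[kept %in% drop] <- 0L

  prob <- predict_probability(clf, images$actin)
  cdr <- segment_cdrs(prob, threshold = threshold,
                      closing_diameter = closing_diameter, min_area = min_area)
  counts <- count_cdr_pixels_per_cell(cdr, kept)
  score <- score_image(records, counts, slope,
                       min_cells = min_cells, min_focus_slope = min_focus_slope)
  list(score = score, cells = records, per_cell_pixels = counts,
       cell_labels = shrunk, kept_cells = kept, cdr = cdr)
}

#' Run the pipeline over a generated (or loaded) set of fields
#'
#' @param fields Tibble of fields as produced by [generate_plate()] (identity
#'   columns plus an `images` list column).
#' @param clf A trained pixel classifier.
#' @param ... Passed to [process_field()].
#'
#' @return A per-image tibble: identity columns plus `count_cells`,
#'   `focus_slope`, `raw_score`, `qc_pass`, `qc_reason`.
#' @export
screen_image_scores <- function(fields, clf, ...) {
  rows <- purrr::pmap(list(fields$images, seq_len(nrow(fields))),
                      function(img, i) {
    res <- process_field(img, clf, ...)
    dplyr::bind_cols(
      fields[i, setdiff(names(fields), c("images", "truth"))], res$score)
  })
  dplyr::bind_rows(rows)
}

#' Per-image scores from generator ground truth
#'
#' The scoring-level fast path: per-image raw scores computed directly from
#' the generator's ground-truth per-cell CDR pixel counts (all cells kept, no
#' imaging noise, perfect focus). Used to study the normalization and
#' aggregation stages at screen scale without rendering or classifying
#' images.
#'
#' @param fields Tibble from [generate_plate()] (a `truth` list column is
#'   required; `render = FALSE` suffices).
#'
#' @return A per-image tibble compatible with [normalize_plate()].
#' @export
truth_image_scores <- function(fields) {
  rows <- purrr::map2(fields$truth, seq_len(nrow(fields)), function(tr, i) {
    n <- length(tr$per_cell_cdr_pixels)
    dplyr::bind_cols(
      fields[i, setdiff(names(fields), c("images", "truth"))],
      tibble::tibble(
        count_cells = n,
        focus_slope = 0,
        raw_score = if (n > 0) mean(tr$per_cell_cdr_pixels) else NA_real_,
        qc_pass = n >= 20,
        qc_reason = ifelse(n >= 20, "pass", "too_few_cells")
      ))
  })
  dplyr::bind_rows(rows)
}

#' Run a complete simulated screen
#'
#' Convenience wrapper: generate the plate(s), train the pixel classifier on
#' dedicated training fields of the negative control, score every image,
#' normalize per plate, aggregate per siRNA and call gene-level hits.
#'
#' @param layout Plate layout tibble.
#' @param negative_control_id Treatment id of the negative control.
#' @param fields_per_well Fields per well.
#' @param plates Plate identifiers (replicates).
#' @param cfg Generator configuration.
#' @param rng_seed Master seed.
#' @param clf Optional pre-trained classifier; if `NULL`, one is trained on
#'   `n_train_fields` extra negative-control fields.
#' @param n_train_fields Number of training fields when `clf` is `NULL`.
#' @param hit_threshold,min_sirnas Hit-calling parameters.
#'
#' @return A list of class `cdr_screen`: `images`, `treatments`, `hits`,
#'   `clf`.
#' @export
simulate_screen <- function(layout, negative_control_id,
                            fields_per_well = 9, plates = "P1",
                            cfg = synth_config(), rng_seed = 1,
                            clf = NULL, n_train_fields = 10,
                            hit_threshold = 0.4, min_sirnas = 2) {
  validate_layout(layout)
  if (is.null(clf)) {
    ctrl <- layout[layout$role == "negative_control", ][1, ]
    train_fields <- generate_plate(ctrl, fields_per_well = n_train_fields,
                                   cfg = cfg, rng_seed = rng_seed + 1,
                                   plates = "TRAIN")
    labelled <- purrr::map2(train_fields$images, train_fields$truth,
                            function(img, tr) {
      list(image = img$actin,
           labels = derive_training_labels(tr, img$actin, seed = rng_seed))
    })
    clf <- train_pixel_classifier(labelled, seed = rng_seed)
  }
  fields <- generate_plate(layout, fields_per_well = fields_per_well,
                           cfg = cfg, rng_seed = rng_seed, plates = plates)
  images <- screen_image_scores(fields, clf)
  images <- normalize_plate(images, negative_control_id)
  treatments <- aggregate_treatments(images, hit_threshold = hit_threshold)
  hits <- call_hits(treatments, threshold = hit_threshold,
                    min_sirnas = min_sirnas)
  structure(list(images = images, treatments = treatments, hits = hits,
                 clf = clf),
            class = "cdr_screen")
}

#' @export
print.cdr_screen <- function(x, ...) {
  cat("<cdr_screen>\n")
  cat("  images scored:", nrow(x$images),
      sprintf("(%d QC-passing)", sum(x$images$qc_pass)), "\n")
  cat("  treatments:", nrow(x$treatments), "  genes:", nrow(x$hits), "\n")
  cat("  validated genes:", sum(x$hits$validated), "\n")
  invisible(x)
}

#' @rdname simulate_screen
#' @param x,object A `cdr_screen`.
#' @param ... Unused.
#' @method tidy cdr_screen
#' @export
tidy.cdr_screen <- function(x, ...) x$treatments

#' @rdname simulate_screen
#' @method glance cdr_screen
#' @export
glance.cdr_screen <- function(x, ...) {
  tibble::tibble(
    n_images = nrow(x$images),
    n_qc_pass = sum(x$images$qc_pass),
    n_treatments = nrow(x$treatments),
    n_inconclusive = sum(x$treatments$inconclusive),
    n_genes = nrow(x$hits),
    n_validated = sum(x$hits$validated)
  )
}

#' Cell-level CDR recognition quality against ground truth
#'
#' Runs the full pipeline on held-out synthetic fields and compares, per kept
#' cell, the pipeline's CDR call (CDR pixel count > 0) with the generator's
#' ground-truth `cdr_positive` flag. Pipeline cells are matched to
#' ground-truth cells by majority pixel overlap.
#'
#' @param fields Held-out fields tibble from [generate_plate()] (rendered).
#' @param clf A trained pixel classifier.
#' @param ... Passed to [process_field()].
#'
#' @return A one-row tibble: `tpr`, `fpr`, `n_pos`, `n_neg`, `n_cells`.
#' @export
evaluate_recognition <- function(fields, clf, ...) {
  tp <- fp <- n_pos <- n_neg <- 0L
  for (i in seq_len(nrow(fields))) {
    res <- process_field(fields$images[[i]], clf, ...)
    truth <- fields$truth[[i]]
    kept <- res$kept_cells
    for (lb in as.integer(names(res$per_cell_pixels))) {
      overlap <- truth$cell_labels[kept == lb]
      overlap <- overlap[overlap > 0L]
      if (!length(overlap)) next
      gt <- as.integer(names(which.max(table(overlap))))
      called <- res$per_cell_pixels[[as.character(lb)]] > 0L
      if (truth$cdr_positive[[as.character(gt)]]) {
        n_pos <- n_pos + 1L
        tp <- tp + called
      } else {
        n_neg <- n_neg + 1L
        fp <- fp + called
      }
    }
  }
  tibble::tibble(tpr = tp / n_pos, fpr = fp / n_neg,
                 n_pos = n_pos, n_neg = n_neg, n_cells = n_pos + n_neg)
}
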