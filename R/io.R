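# Reading and writing the pipeline's on-disk formats: 16-bit single-channel
# TIFFs (one file per channel per field, named {plate}_{well}_{field}_{channel}
# .tif), plate-layout CSVs, track CSVs and the persisted classifier.

#' Write / read a 12-bit grey image as 16-bit TIFF
#'
#' Grey values (integers in 0..65535; the screen's data use 0..4095) are
#' stored losslessly in a single-channel 16-bit TIFF.
#'
#' @param image Numeric matrix of integer grey values.
#' @param path Output file path.
#' @return `write_grey_tiff` returns `path` invisibly; `read_grey_tiff`
#'   returns the integer grey-value matrix.
#' @export
write_grey_tiff <- function(image, path) {
  assert_image(image)
  if (min(image) < 0 || max(image) > 65535) {
    abort("Grey values must lie in [0, 65535] for 16-bit storage.")
  }
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_grey_tiff
#' @export
read_grey_tiff <- function(path) {
  v <- tiff::readTIFF(path)
  matrix(as.integer(round(v * 65535)), nrow(v), ncol(v))
}

field_file <- function(dir, plate, well, field, channel) {
  file.path(dir, sprintf("%s_%s_%d_%s.tif", plate, well, field, channel))
}

#' Write / read the channel TIFFs of generated fields
#'
#' @param fields Tibble from [generate_plate()] (with rendered images).
#' @param dir Output directory (created if needed).
#' @return `write_field_images` returns the file paths invisibly.
#' @export
write_field_images <- function(fields, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::pmap(
    list(fields$images, fields$plate, fields$well, fields$field),
    function(img, plate, well, field) {
      vapply(names(img), function(ch) {
        p <- field_file(dir, plate, well, field, ch)
        write_grey_tiff(img[[ch]], p)
        p
      }, character(1))
    })
  invisible(unlist(paths))
}

#' @rdname write_field_images
#' @param plate,well,field Identity of the field to read.
#' @export
read_field_images <- function(dir, plate, well, field) {
  chans <- c("actin", "membrane", "nucleus")
  out <- lapply(chans, function(ch) {
    read_grey_tiff(field_file(dir, plate, well, field, ch))
  })
  names(out) <- chans
  out
}

#' Write / read a plate layout CSV
#'
#' Columns: `well,treatment_id,gene,role,cdr_suppression,n_cells_mean,
#' defocus_sigma,saturate_fraction`.
#'
#' @param layout Layout tibble (see [well_spec()]).
#' @param path CSV path.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout, require_negative_control = FALSE)
  readr::write_csv(layout, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  layout <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              well = "c", treatment_id = "c", gene = "c",
                              role = "c", .default = "d"))
  validate_layout(layout, require_negative_control = FALSE)
  layout
}

#' Write / read a tracks CSV (`track_id,t_min,x,y`)
#'
#' @param tracks Tracks tibble.
#' @param path CSV path.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tracks[, c("track_id", "t_min", "x", "y")], path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(track_id = "c", .default = "d"))
}

#' Persist / restore a trained pixel classifier
#'
#' The classifier is stored as a single versioned RDS file holding the
#' serialized tree ensemble (xgboost raw format) plus the feature
#' specification and training metadata.
#'
#' @param clf A [train_pixel_classifier()] model.
#' @param path Output file.
#' @export
save_classifier <- function(clf, path) {
  if (!inherits(clf, "cdr_pixel_classifier")) {
    abort("`clf` must be a cdr_pixel_classifier.")
  }
  payload <- clf
  payload$booster <- xgboost::xgb.save.raw(clf$booster)
  payload$format_version <- 1L
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$format_version) || payload$format_version != 1L) {
    abort("Unsupported classifier file version.")
  }
  payload$booster <- xgboost::xgb.load.raw(payload$booster)
  payload$format_version <- NULL
  structure(payload, class = "cdr_pixel_classifier")
}
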