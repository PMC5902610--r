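# Supervised pixel classification of CDR versus background pixels, and
# post-processing of the probability map into CDR objects.

shift_mat <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  ri <- clamp(seq_len(h) + dr, 1L, h)
  ci <- clamp(seq_len(w) + dc, 1L, w)
  x[ri, ci]
}

#' Per-pixel texture features for CDR classification
#'
#' Computes, for each smoothing scale, the Gaussian-smoothed intensity, the
#' gradient magnitude, the Laplacian, and the two eigenvalues of the Hessian
#' (largest first by signed value). Ring-shaped structures such as CDRs
#' produce strongly negative second derivatives across the ring at matching
#' scales, which separates them from linear stress fibres and flat cytoplasm.
#' Derivatives are central finite differences of the smoothed image.
#'
#' The feature axis order is fixed: for each scale in `scales` (in the given
#' order) the five features `gauss`, `gradmag`, `laplacian`, `hess_hi`,
#' `hess_lo`; names are stored in the third dimnames.
#'
#' @param actin Numeric matrix (actin channel).
#' @param scales Smoothing scales (Gaussian sigma, px).
#'
#' @return A numeric array `height x width x (5 * length(scales))`.
#' @export
extract_pixel_features <- function(actin, scales = c(0.7, 1.6, 3.5, 5.0)) {
  assert_image(actin, "actin")
  if (length(scales) == 0L) abort("`scales` must be non-empty.")
  h <- nrow(actin); w <- ncol(actin)
  feats <- array(0, dim = c(h, w, 5L * length(scales)))
  nm <- character(5L * length(scales))
  k <- 0L
  for (s in scales) {
    g <- gauss_smooth(actin, s)
    gx <- (shift_mat(g, 0L, 1L) - shift_mat(g, 0L, -1L)) / 2
    gy <- (shift_mat(g, 1L, 0L) - shift_mat(g, -1L, 0L)) / 2
    gxx <- shift_mat(g, 0L, 1L) - 2 * g + shift_mat(g, 0L, -1L)
    gyy <- shift_mat(g, 1L, 0L) - 2 * g + shift_mat(g, -1L, 0L)
    gxy <- (shift_mat(gx, 1L, 0L) - shift_mat(gx, -1L, 0L)) / 2
    tr <- gxx + gyy
    disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
    feats[, , k + 1L] <- g
    feats[, , k + 2L] <- sqrt(gx^2 + gy^2)
    feats[, , k + 3L] <- tr
    feats[, , k + 4L] <- (tr + disc) / 2
    feats[, , k + 5L] <- (tr - disc) / 2
    nm[k + seq_len(5L)] <- paste0(c("gauss", "gradmag", "laplacian",
                                    "hess_hi", "hess_lo"), "_s", s)
    k <- k + 5L
  }
  dimnames(feats) <- list(NULL, NULL, nm)
  feats
}

#' Derive sparse training labels from generator ground truth
#'
#' Replaces manual pixel labelling for synthetic data: the ground-truth CDR
#' mask dilated by one pixel becomes the CDR class, and background pixels are
#' sampled from the remainder (half uniformly, half weighted by intensity so
#' that bright non-CDR structures such as stress fibres are well represented).
#'
#' @param truth Ground-truth list from [render_image_set()].
#' @param actin Actin channel used for intensity-weighted background sampling.
#' @param n_background Number of background pixels to sample (default: twice
#'   the number of CDR pixels).
#' @param seed Seed for the background sampling.
#'
#' @return A sparse label matrix: 0 = unlabelled, 1 = CDR, 2 = background.
#' @export
derive_training_labels <- function(truth, actin, n_background = NULL, seed = 1) {
  assert_image(actin, "actin")
  cdr <- EBImage::dilate(EBImage::Image(truth$cdr_mask * 1),
                         EBImage::makeBrush(3, "box"))
  cdr <- matrix(as.numeric(cdr) > 0, nrow(actin), ncol(actin))
  labels <- matrix(0L, nrow(actin), ncol(actin))
  labels[cdr] <- 1L
  bg_idx <- which(!cdr)
  n_cdr <- sum(cdr)
  if (is.null(n_background)) n_background <- max(2L * n_cdr, 1000L)
  n_background <- min(n_background, length(bg_idx))
  with_seed(seed, {
    n_unif <- ceiling(n_background / 2)
    pick_u <- sample(bg_idx, n_unif)
    wgt <- as.numeric(actin[bg_idx])
    wgt <- wgt - min(wgt) + 1
    pick_w <- sample(bg_idx, n_background - n_unif, prob = wgt)
    labels[unique(c(pick_u, pick_w))] <- 2L
  })
  labels
}

#' Train the two-class CDR pixel classifier
#'
#' Fits a random forest (an ensemble of `n_trees` bagged decision trees, each
#' grown on a subsample of pixels and a random feature subset per split) on
#' the features of the labelled pixels. The trees are regression trees on the
#' CDR-class indicator with unshrunk leaves, so each leaf stores the exact
#' class fraction of its training pixels and the ensemble prediction is the
#' vote fraction, a probability in `[0, 1]`. The forest is built and evaluated
#' with the xgboost engine (`num_parallel_tree`), which shares the training
#' contract of classical random-forest implementations but predicts orders of
#' magnitude faster on full images.
#'
#' @param labelled A list of `list(image =, labels =)` pairs, where `labels`
#'   is a sparse label matrix (0 = unlabelled, 1 = CDR, 2 = background).
#' @param seed Integer seed; fixes subsampling so training is reproducible.
#' @param scales Feature scales passed to [extract_pixel_features()].
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth.
#' @param subsample Row subsampling fraction per tree.
#' @param colsample Feature subsampling fraction per split.
#'
#' @return An object of class `cdr_pixel_classifier`.
#' @export
train_pixel_classifier <- function(labelled, seed = 1,
                                   scales = c(0.7, 1.6, 3.5, 5.0),
                                   n_trees = 100, max_depth = 14,
                                   subsample = 0.632, colsample = 0.25) {
  if (!length(labelled)) abort("`labelled` must contain at least one image.")
  X <- list(); y <- list()
  for (item in labelled) {
    lab <- item$labels
    sel <- which(lab > 0L)
    if (!length(sel)) next
    fs <- extract_pixel_features(item$image, scales)
    fm <- matrix(fs, nrow = prod(dim(fs)[1:2]), ncol = dim(fs)[3])
    X[[length(X) + 1L]] <- fm[sel, , drop = FALSE]
    y[[length(y) + 1L]] <- as.integer(lab[sel] == 1L)
  }
  X <- do.call(rbind, X)
  y <- unlist(y)
  if (is.null(X) || length(unique(y)) < 2L) {
    abort("Training labels must contain both the CDR and the background class.")
  }
  params <- list(objective = "reg:squarederror", eta = 1, lambda = 0, alpha = 0,
                 max_depth = max_depth, subsample = subsample,
                 colsample_bynode = colsample, num_parallel_tree = n_trees,
                 tree_method = "hist", nthread = 1, seed = as.integer(seed))
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 1,
                                verbose = 0)
  structure(list(
    booster = booster,
    feature_names = dimnames(extract_pixel_features(
      matrix(0, 64, 64), scales))[[3]],
    scales = scales, n_trees = n_trees, max_depth = max_depth,
    seed = as.integer(seed), n_train = length(y),
    class_balance = mean(y),
    class_names = c("CDR", "Background")
  ), class = "cdr_pixel_classifier")
}

#' @export
print.cdr_pixel_classifier <- function(x, ...) {
  cat("<cdr_pixel_classifier>\n")
  cat("  trees:", x$n_trees, " max depth:", x$max_depth, "\n")
  cat("  features:", length(x$feature_names),
      "(scales", paste(x$scales, collapse = ", "), ")\n")
  cat("  training pixels:", x$n_train,
      sprintf("(CDR fraction %.2f)", x$class_balance), "\n")
  invisible(x)
}

#' @rdname train_pixel_classifier
#' @param x,object A `cdr_pixel_classifier`.
#' @param ... Unused.
#' @method tidy cdr_pixel_classifier
#' @export
tidy.cdr_pixel_classifier <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(feature = x$feature_names[as.integer(
    sub("^f", "", imp$Feature)) + 1L],
    gain = imp$Gain, cover = imp$Cover, frequency = imp$Frequency)
}

#' @rdname train_pixel_classifier
#' @method glance cdr_pixel_classifier
#' @export
glance.cdr_pixel_classifier <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, max_depth = x$max_depth,
                 n_features = length(x$feature_names),
                 n_train_pixels = x$n_train, cdr_fraction = x$class_balance,
                 seed = x$seed)
}

#' Per-pixel CDR probability image
#'
#' Applies the trained classifier to an actin image and returns the CDR-class
#' probability at every pixel, in `[0, 1]`.
#'
#' @param clf A [train_pixel_classifier()] model.
#' @param actin Numeric matrix (actin channel).
#'
#' @return A numeric matrix of probabilities with the shape of `actin`.
#' @export
predict_probability <- function(clf, actin) {
  if (!inherits(clf, "cdr_pixel_classifier")) {
    abort("`clf` must be a cdr_pixel_classifier.")
  }
  assert_image(actin, "actin")
  fs <- extract_pixel_features(actin, clf$scales)
  if (dim(fs)[3] != length(clf$feature_names)) {
    abort("Feature stack does not match the classifier's training spec.")
  }
  fm <- matrix(fs, nrow = prod(dim(fs)[1:2]), ncol = dim(fs)[3])
  p <- predict(clf$booster, xgboost::xgb.DMatrix(fm, nthread = 1))
  matrix(clamp(p, 0, 1), nrow(actin), ncol(actin))
}

#' Post-process a probability image into CDR objects
#'
#' Thresholds the probability image (inclusive at the threshold), applies a
#' morphological closing with a disk structuring element to connect
#' neighbouring CDR pixels, labels 8-connected components, and removes objects
#' smaller than `min_area` pixels (areas measured after closing).
#'
#' @param prob Probability matrix in `[0, 1]`.
#' @param threshold Probability cut-off (default 0.51; the exact value is not
#'   critical because the screen's final score is normalized to the negative
#'   control).
#' @param closing_diameter Diameter (px) of the disk structuring element.
#' @param min_area Minimum object area in pixels.
#'
#' @return A list of class `cdr_objects` with `label_map` (integer matrix,
#'   labels `1..N`) and `areas` (named integer vector).
#' @export
segment_cdrs <- function(prob, threshold = 0.51, closing_diameter = 7,
                         min_area = 25) {
  assert_image(prob, "prob")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must lie in (0, 1).")
  if (min(prob) < 0 || max(prob) > 1) abort("`prob` must lie in [0, 1].")
  binary <- prob >= threshold
  if (any(binary) && closing_diameter > 1) {
    brush <- EBImage::makeBrush(closing_diameter, "disc")
    closed <- EBImage::closing(EBImage::Image(binary * 1), brush)
    binary <- matrix(as.numeric(closed) > 0, nrow(prob), ncol(prob))
  }
  lab <- label_components_cpp(binary, eight = TRUE)
  n <- max(lab)
  if (n > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(sizes >= min_area)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)
    nz <- lab > 0L
    lab[nz] <- remap[lab[nz]]
    areas <- sizes[keep]
    names(areas) <- as.character(seq_along(keep))
  } else {
    areas <- integer(0)
  }
  structure(list(label_map = lab, areas = as.integer(areas),
                 threshold = threshold, closing_diameter = closing_diameter,
                 min_area = min_area),
            class = "cdr_objects")
}

#' Count CDR pixels inside each kept cell
#'
#' @param cdr A `cdr_objects` result (or a CDR label matrix).
#' @param kept_cells Integer label matrix containing only the kept (shrunk,
#'   filtered) cell objects.
#'
#' @return A named integer vector: CDR pixel count for every cell label in
#'   `kept_cells` (zeros included). CDR pixels outside kept cells are ignored.
#' @export
count_cdr_pixels_per_cell <- function(cdr, kept_cells) {
  cdr_map <- if (inherits(cdr, "cdr_objects")) cdr$label_map else cdr
  assert_same_dim(cdr_map, kept_cells, "`cdr` and `kept_cells`")
  labs <- sort(unique(kept_cells[kept_cells > 0L]))
  counts <- integer(length(labs))
  names(counts) <- as.character(labs)
  if (length(labs)) {
    inside <- cdr_map > 0L & kept_cells > 0L
    if (any(inside)) {
      tab <- table(kept_cells[inside])
      counts[names(tab)] <- as.integer(tab)
    }
  }
  counts
}
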