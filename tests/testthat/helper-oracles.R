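# Brute-force oracles and geometric fixtures used across tests. These stay
# independent of the package's implementation paths they check.

# rasterized disk mask: pixels whose centre lies within r of ctr (1-based)
draw_disk <- function(h, w, ctr, r) {
  D <- sqrt(outer((seq_len(h) - ctr[1])^2, (seq_len(w) - ctr[2])^2, `+`))
  D <= r
}

# brute-force binary dilation by a structuring-element offset list
se_offsets <- function(mask_se) {
  ctr <- (dim(mask_se) + 1) / 2
  idx <- which(mask_se > 0, arr.ind = TRUE)
  cbind(idx[, 1] - ctr[1], idx[, 2] - ctr[2])
}

bf_dilate <- function(mask, offs) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    r <- idx[, 1] + offs[k, 1]
    c <- idx[, 2] + offs[k, 2]
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    out[cbind(r[ok], c[ok])] <- TRUE
  }
  out
}

bf_erode <- function(mask, offs) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(TRUE, h, w)
  for (k in seq_len(nrow(offs))) {
    shifted <- matrix(FALSE, h, w)
    rs <- seq_len(h) - offs[k, 1]
    cs <- seq_len(w) - offs[k, 2]
    ok_r <- rs >= 1 & rs <= h
    ok_c <- cs >= 1 & cs <= w
    shifted[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
    out <- out & shifted
  }
  out
}

bf_closing <- function(mask, mask_se) {
  offs <- se_offsets(mask_se)
  bf_erode(bf_dilate(mask, offs), offs)
}

# brute-force 8-connected labeling by repeated flood fill
bf_label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > h || jj < 1 || jj > w) next
        if (mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# a small, fast generator configuration for pipeline-level unit tests
fast_cfg <- function(...) synth_config(...)

# standard negative-control well for generator tests
ctrl_well <- function(...) {
  well_spec("A01", "siEGFP", "EGFP", role = "negative_control", ...)
}

# train a small classifier once per test run and cache it
cached_classifier <- local({
  clf <- NULL
  function(n_fields = 3, seed = 400) {
    if (is.null(clf)) {
      fields <- generate_plate(ctrl_well(), fields_per_well = n_fields,
                               cfg = fast_cfg(), rng_seed = seed,
                               plates = "TRAIN")
      labelled <- purrr::map2(fields$images, fields$truth, function(img, tr) {
        list(image = img$actin,
             labels = derive_training_labels(tr, img$actin, seed = seed))
      })
      clf <<- train_pixel_classifier(labelled, seed = seed)
    }
    clf
  }
})

# Gaussian blur via EBImage directly (independent of package internals)
gauss_smooth_for_test <- function(x, sigma) {
  matrix(as.numeric(EBImage::gblur(x, sigma)), nrow(x), ncol(x))
}
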