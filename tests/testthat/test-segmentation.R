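# Robust thresholding, nucleus segmentation, focus metric, seeded watershed,
# per-object shrinking and the cell filters.

test_that("robust background threshold follows trimmed mean + 2 sd", {
  expect_equal(robust_background_threshold(matrix(100, 10, 10)), 100)

  # 5 bright outliers among 100 pixels fall inside the 5% upper trim
  img <- matrix(c(rep(100, 95), rep(4000, 5)), 10, 10)
  expect_equal(robust_background_threshold(img), 100)

  # near-normal population: compare with truncated-normal moments computed
  # by numerical integration (independent of the sort/trim code path)
  set.seed(1)
  img <- matrix(rnorm(10000, 200, 10), 100, 100)
  thr <- robust_background_threshold(img)
  a <- qnorm(0.05); b <- qnorm(0.95)
  z <- integrate(function(x) x * dnorm(x), a, b)$value / 0.9
  z2 <- integrate(function(x) x^2 * dnorm(x), a, b)$value / 0.9
  expected <- 200 + 10 * z + 2 * 10 * sqrt(z2 - z^2)
  expect_equal(thr, expected, tolerance = 0.01)
  expect_true(thr >= 215 && thr <= 225)
})

test_that("nucleus segmentation labels bright components above threshold", {
  blank <- matrix(80, 64, 64)
  expect_equal(max(segment_nuclei(blank)), 0L)

  img <- matrix(50, 128, 128)
  img[draw_disk(128, 128, c(40, 40), 10)] <- 2000
  img[draw_disk(128, 128, c(90, 90), 10)] <- 2000
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 2L)

  # a dark internal ring (chromatin-poor zone) is recovered by hole filling
  img2 <- matrix(50, 128, 128)
  disk <- draw_disk(128, 128, c(64, 64), 14)
  hole <- draw_disk(128, 128, c(64, 64), 7) & !draw_disk(128, 128, c(64, 64), 5)
  img2[disk] <- 2000
  img2[hole] <- 50
  lab2 <- segment_nuclei(img2)
  expect_equal(max(lab2), 1L)
  expect_true(all(lab2[disk] == 1L))
  # oracle: without filling, the dark ring isolates the core as a second
  # 8-connected component
  thr <- robust_background_threshold(img2)
  expect_equal(max(bf_label8(img2 > thr)), 2L)
})

test_that("small components are removed by the minimum nucleus size", {
  img <- matrix(50, 64, 64)
  img[draw_disk(64, 64, c(20, 20), 8)] <- 2000   # ~200 px, kept
  img[30:32, 50:52] <- 2000                      # 9 px, dropped
  expect_equal(max(segment_nuclei(img, min_size = 50)), 1L)
})

test_that("focus slope is ~0 for white noise and decreases under blur", {
  set.seed(42)
  noise <- matrix(runif(256 * 256, 0, 1000), 256, 256)
  s_noise <- power_log_log_slope(noise)
  expect_lt(abs(s_noise), 0.3)

  fs <- render_image_set(ctrl_well(), 1, fast_cfg(), rng_seed = 12)
  img <- fs$images$nucleus
  s0 <- power_log_log_slope(img)
  s_blur <- power_log_log_slope(gauss_smooth_for_test(img, 3))
  expect_lt(s_blur, s0)
})

test_that("focus slope is invariant to affine intensity changes", {
  fs <- render_image_set(ctrl_well(), 1, fast_cfg(), rng_seed = 13)
  img <- fs$images$nucleus
  s0 <- power_log_log_slope(img)
  expect_equal(power_log_log_slope(img + 500), s0, tolerance = 1e-8)
  expect_equal(power_log_log_slope(img * 3.7), s0, tolerance = 1e-8)
})

test_that("a constant image has an undefined focus slope", {
  expect_warning(s <- power_log_log_slope(matrix(7, 64, 64)), "Constant")
  expect_true(is.na(s))
})

test_that("in-focus fields pass the -2 QC cut and defocused fields fail", {
  w_focus <- ctrl_well()
  w_blur <- ctrl_well(defocus_sigma = 2.5)
  s_focus <- power_log_log_slope(
    render_image_set(w_focus, 1, fast_cfg(), rng_seed = 19)$images$nucleus)
  s_blur <- power_log_log_slope(
    render_image_set(w_blur, 1, fast_cfg(), rng_seed = 19)$images$nucleus)
  expect_gte(s_focus, -2)
  expect_lt(s_blur, -2)
})

test_that("seeded watershed partitions the foreground and contains seeds", {
  # one nucleus inside one uniform bright body
  memb <- matrix(0, 96, 96)
  body <- draw_disk(96, 96, c(48, 48), 30)
  memb[body] <- 1500
  nuc <- matrix(0L, 96, 96)
  nuc[draw_disk(96, 96, c(48, 48), 8)] <- 1L
  cells <- segment_cells(nuc, memb, bg_sigma = 200, smooth_sigma = 0)
  expect_true(all(cells[nuc == 1L] == 1L))
  expect_true(all(cells[body] == 1L))

  # two nuclei in one connected blob: the blob is partitioned between them
  memb2 <- matrix(0, 96, 160)
  blob <- draw_disk(96, 160, c(48, 55), 30) | draw_disk(96, 160, c(48, 105), 30)
  memb2[blob] <- 1500
  nuc2 <- matrix(0L, 96, 160)
  nuc2[draw_disk(96, 160, c(48, 55), 7)] <- 1L
  nuc2[draw_disk(96, 160, c(48, 105), 7)] <- 2L
  cells2 <- segment_cells(nuc2, memb2, bg_sigma = 200, smooth_sigma = 0)
  expect_setequal(unique(as.integer(cells2[blob])), c(1L, 2L))
  expect_true(all(cells2[nuc2 == 1L] == 1L))
  expect_true(all(cells2[nuc2 == 2L] == 2L))
  # labels partition: disjoint by construction of a label map; union covers blob
  expect_true(all(cells2[blob] > 0L))

  # a nucleus with no membrane foreground keeps (at least) its own footprint
  memb3 <- matrix(0, 64, 64)
  nuc3 <- matrix(0L, 64, 64)
  foot <- draw_disk(64, 64, c(32, 32), 6)
  nuc3[foot] <- 1L
  cells3 <- segment_cells(nuc3, memb3, bg_sigma = 200)
  expect_true(all(cells3[foot] == 1L))

  # no nuclei -> no cells
  expect_equal(max(segment_cells(matrix(0L, 32, 32), matrix(0, 32, 32))), 0L)
})

test_that("shrinking erodes each object by a Euclidean disk", {
  lab <- matrix(0L, 64, 64)
  lab[draw_disk(64, 64, c(32, 32), 20)] <- 1L
  shr <- shrink_cells(lab, 5)
  oracle <- sum(draw_disk(64, 64, c(32, 32), 15))
  expect_lt(abs(sum(shr == 1L) - oracle) / oracle, 0.05)

  # a ribbon thinner than 11 px is emptied by a radius-5 erosion
  thin <- matrix(0L, 32, 64)
  thin[12:21, 5:60] <- 1L
  expect_equal(max(shrink_cells(thin, 5)), 0L)

  expect_identical(shrink_cells(lab, 0), lab)
})

test_that("shrinking is monotone and composes sub-additively", {
  fs <- render_image_set(ctrl_well(), 1, fast_cfg(), rng_seed = 44,
                         render = FALSE)
  lab <- fs$truth$cell_labels
  a2 <- shrink_cells(lab, 2)
  a5 <- shrink_cells(lab, 5)
  area <- function(m) tabulate(m[m > 0L], nbins = max(lab))
  expect_true(all(area(a2) <= area(lab)))
  expect_true(all(area(a5) <= area(a2)))
  a23 <- shrink_cells(a2, 3)
  # composed erosions agree with the single erosion up to rasterization
  expect_true(all(abs(area(a23) - area(a5)) <= 0.03 * area(a5)))
})

test_that("cell filters apply the screen's strict rejection boundaries", {
  mk <- function(area_dims, value, n_sat = 0) {
    h <- area_dims[1]; w <- area_dims[2]
    lab <- matrix(0L, h + 4, w + 4)
    lab[3:(h + 2), 3:(w + 2)] <- 1L
    act <- matrix(0, h + 4, w + 4)
    px <- which(lab == 1L)
    act[px] <- value
    if (n_sat > 0) act[px[seq_len(n_sat)]] <- 4095
    list(lab = lab, act = act)
  }
  # 49x51 = 2499 px: rejected as too small despite bright staining
  f <- mk(c(49, 51), 300)
  rec <- filter_cells(f$lab, f$act)
  expect_false(rec$kept)
  expect_equal(rec$reject_reason, "too_small")

  # 50x50 = 2500 px with mean exactly 200: all keep-side boundaries inclusive
  f <- mk(c(50, 50), 200)
  rec <- filter_cells(f$lab, f$act)
  expect_equal(rec$area_px, 2500L)
  expect_equal(rec$mean_actin, 200)
  expect_true(rec$kept)

  # exactly 500 saturated pixels: still kept
  f <- mk(c(50, 50), 300, n_sat = 500)
  rec <- filter_cells(f$lab, f$act)
  expect_equal(rec$saturated_px, 500L)
  expect_true(rec$kept)

  # 501 saturated pixels: rejected as too saturated
  f <- mk(c(60, 60), 300, n_sat = 501)
  rec <- filter_cells(f$lab, f$act)
  expect_equal(rec$reject_reason, "too_saturated")

  # mean 199.9 (just below 200): rejected as too dim
  f <- mk(c(60, 60), 199.9)
  rec <- filter_cells(f$lab, f$act)
  expect_equal(rec$reject_reason, "too_dim")

  # rejection order: size outranks dim and saturated
  f <- mk(c(40, 40), 150, n_sat = 600)
  rec <- filter_cells(f$lab, f$act)
  expect_equal(rec$reject_reason, "too_small")
})

test_that("nucleus counts match ground truth on in-focus fields", {
  ok <- vapply(1:10, function(s) {
    fs <- render_image_set(ctrl_well(), 1, fast_cfg(), rng_seed = 600 + s)
    max(segment_nuclei(fs$images$nucleus)) == max(fs$truth$nucleus_labels)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
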