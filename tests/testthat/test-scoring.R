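# Per-image scoring, QC boundaries, plate normalization, aggregation and hit
# calling.

mk_cells <- function(n_kept, n_rejected = 0) {
  tibble::tibble(
    label = seq_len(n_kept + n_rejected),
    area_px = 3000L, mean_actin = 400, saturated_px = 0L,
    kept = c(rep(TRUE, n_kept), rep(FALSE, n_rejected)),
    reject_reason = c(rep("none", n_kept), rep("too_small", n_rejected))
  )
}

counts_for <- function(cells, value) {
  counts <- rep(value, length.out = sum(cells$kept))
  names(counts) <- as.character(cells$label[cells$kept])
  counts
}

test_that("raw score is the mean CDR pixel count over kept cells", {
  cells <- mk_cells(2)
  sc <- score_image(cells, counts_for(cells, c(10, 30)), focus_slope = -1)
  expect_equal(sc$raw_score, 20)
  expect_false(sc$qc_pass)   # only 2 kept cells
  expect_equal(sc$qc_reason, "too_few_cells")

  # rejected cells do not enter the average
  cells2 <- mk_cells(20, n_rejected = 5)
  counts <- counts_for(cells2, 7)
  sc2 <- score_image(cells2, counts, focus_slope = -1)
  expect_equal(sc2$raw_score, 7)
  expect_equal(sc2$count_cells, 20L)
  expect_true(sc2$qc_pass)
})

test_that("QC boundaries are strict: 20 cells and slope -2 pass", {
  c19 <- mk_cells(19); c20 <- mk_cells(20)
  expect_equal(score_image(c19, counts_for(c19, 1), -1)$qc_reason,
               "too_few_cells")
  expect_true(score_image(c20, counts_for(c20, 1), -1)$qc_pass)
  expect_equal(score_image(c20, counts_for(c20, 1), -2.1)$qc_reason,
               "out_of_focus")
  expect_true(score_image(c20, counts_for(c20, 1), -2.0)$qc_pass)
  # undefined slope counts as out of focus
  expect_equal(score_image(c20, counts_for(c20, 1), NA_real_)$qc_reason,
               "out_of_focus")
})

test_that("an image with zero kept cells has an undefined raw score", {
  cells <- mk_cells(0, n_rejected = 3)
  sc <- score_image(cells, integer(0), focus_slope = -1)
  expect_true(is.na(sc$raw_score))
  expect_false(sc$qc_pass)
})

mk_images <- function(raw, treatment, plate = "P1", qc = TRUE) {
  tibble::tibble(
    plate = plate, well = paste0("W", seq_along(raw)), field = 1L,
    treatment_id = treatment, gene = treatment, role = "sample",
    count_cells = 25L, focus_slope = -1, raw_score = raw,
    qc_pass = qc, qc_reason = ifelse(qc, "pass", "out_of_focus")
  )
}

test_that("plate normalization divides by the negative-control mean", {
  imgs <- dplyr::bind_rows(
    mk_images(c(40, 60), "siEGFP"),
    mk_images(c(10, 50), "siX")
  )
  out <- normalize_plate(imgs, "siEGFP")
  expect_equal(out$ratio_score[out$treatment_id == "siEGFP"], c(0.8, 1.2))
  expect_equal(out$ratio_score[out$treatment_id == "siX"], c(0.2, 1.0))
  # control self-normalization: the control mean ratio is exactly 1
  expect_identical(mean(out$ratio_score[out$treatment_id == "siEGFP"]), 1)
})

test_that("ratio scores are invariant to a plate-wide intensity rescaling", {
  imgs <- dplyr::bind_rows(mk_images(c(40, 60), "siEGFP"),
                           mk_images(c(10, 50, 33), "siX"))
  scaled <- dplyr::mutate(imgs, raw_score = raw_score * 37.5)
  expect_equal(normalize_plate(scaled, "siEGFP")$ratio_score,
               normalize_plate(imgs, "siEGFP")$ratio_score)
})

test_that("plates without usable control images are excluded with a warning", {
  bad <- dplyr::bind_rows(mk_images(c(40, 60), "siEGFP", qc = FALSE),
                          mk_images(c(10), "siX"))
  expect_warning(out <- normalize_plate(bad, "siEGFP"), "Excluding plate")
  expect_equal(nrow(out), 0L)
  # two plates, only one normalizable
  two <- dplyr::bind_rows(
    bad,
    mk_images(c(40, 60), "siEGFP", plate = "P2"),
    mk_images(c(20), "siX", plate = "P2"))
  expect_warning(out2 <- normalize_plate(two, "siEGFP"), "P1")
  expect_setequal(unique(out2$plate), "P2")
  expect_error(normalize_plate(mk_images(10, "siX"), "siEGFP"),
               "negative control")
})

test_that("treatment aggregation averages QC-passing images only", {
  imgs <- dplyr::bind_rows(mk_images(c(40, 40), "siEGFP"),
                           mk_images(c(8, 12, 16), "siX"),
                           mk_images(99, "siDead", qc = FALSE))
  out <- normalize_plate(imgs, "siEGFP")
  tr <- aggregate_treatments(out)
  expect_equal(tr$cdr_score[tr$treatment_id == "siX"],
               mean(c(8, 12, 16) / 40))
  expect_equal(tr$n_images[tr$treatment_id == "siX"], 3L)
  # all images failing QC -> inconclusive, no score
  dead <- tr[tr$treatment_id == "siDead", ]
  expect_true(dead$inconclusive)
  expect_true(is.na(dead$cdr_score))
  # single passing image -> score equals its ratio
  single <- dplyr::bind_rows(mk_images(40, "siEGFP"), mk_images(10, "siY"))
  tr2 <- aggregate_treatments(normalize_plate(single, "siEGFP"))
  expect_equal(tr2$cdr_score[tr2$treatment_id == "siY"], 0.25)
})

test_that("hit calling validates genes with >= 2 of 3 siRNA hits", {
  scores <- tibble::tibble(
    treatment_id = paste0("si", 1:9),
    gene = rep(c("GeneA", "GeneB", "GeneC"), each = 3),
    cdr_score = c(0.30, 0.35, 0.80,   # A: 2 hits -> validated
                  0.40, 0.90, 1.00,   # B: 0.40 is NOT a hit (strict <)
                  0.39, NA, 0.90),    # C: 1 hit of 2 conclusive
    n_images = c(rep(10L, 7), 0L, 10L),
    inconclusive = c(rep(FALSE, 7), TRUE, FALSE),
    is_hit = !is.na(cdr_score) & cdr_score < 0.4
  )
  hits <- call_hits(scores)
  a <- hits[hits$gene == "GeneA", ]
  expect_true(a$validated)
  expect_equal(a$n_hits, 2L)
  expect_false(hits$validated[hits$gene == "GeneB"])
  expect_equal(hits$n_hits[hits$gene == "GeneB"], 0L)
  cc <- hits[hits$gene == "GeneC", ]
  expect_false(cc$validated)
  expect_equal(cc$n_conclusive, 2L)
  # ranking ascends in gene-level mean score
  expect_equal(hits$gene, hits$gene[order(hits$mean_cdr_score)])
})

test_that("fully inconclusive genes are reported as such", {
  scores <- tibble::tibble(
    treatment_id = c("s1", "s2"), gene = "GeneX",
    cdr_score = c(NA_real_, NA_real_), n_images = 0L,
    inconclusive = TRUE, is_hit = FALSE)
  hits <- call_hits(scores)
  expect_true(hits$inconclusive)
  expect_false(hits$validated)
})

test_that("manual CDR score normalizes positive fractions to the control", {
  expect_equal(manual_cdr_score(60, 100, 0.6), 1.0)
  expect_equal(manual_cdr_score(30, 100, 0.6), 0.5)
  expect_equal(manual_cdr_score(0, 100, 0.6), 0.0)
  expect_error(manual_cdr_score(1, 0, 0.5), "n_total")
  expect_error(manual_cdr_score(1, 10, 0), "control_fraction")
})

test_that("scoring recovers known suppression effects across seeds", {
  layout <- dplyr::bind_rows(
    well_spec("A01", "siEGFP", "EGFP", role = "negative_control"),
    well_spec("A02", "si00", "G0", cdr_suppression = 0),
    well_spec("A03", "si25", "G1", cdr_suppression = 0.25),
    well_spec("A04", "si50", "G2", cdr_suppression = 0.5),
    well_spec("A05", "si75", "G3", cdr_suppression = 0.75),
    well_spec("A06", "si100", "G4", cdr_suppression = 1))
  true_supp <- c(0, 0.25, 0.5, 0.75, 1)
  ests <- matrix(NA_real_, 5, 5)
  for (seed in 1:5) {
    fields <- generate_plate(layout, fields_per_well = 9, cfg = fast_cfg(),
                             rng_seed = 9000 + seed,
                             plates = c("P1", "P2", "P3"), render = FALSE)
    tr <- truth_image_scores(fields) |>
      normalize_plate("siEGFP") |>
      aggregate_treatments()
    est <- tr$cdr_score[match(paste0("G", 0:4), tr$gene)]
    ests[seed, ] <- est
    expect_gt(cor(est, 1 - true_supp, method = "spearman"), 0.9)
  }
  # Monte-Carlo verification across the seeds: the estimator is unbiased to
  # within the stated band
  expect_true(all(abs(colMeans(ests) - (1 - true_supp)) <= 0.1))
})

test_that("a null screen calls almost no hits", {
  layout <- dplyr::bind_rows(
    well_spec("A01", "siEGFP", "EGFP", role = "negative_control"),
    purrr::map(1:20, function(i) {
      well_spec(sprintf("B%02d", i), paste0("siNull", i), paste0("N", i))
    }))
  fields <- generate_plate(layout, fields_per_well = 9, cfg = fast_cfg(),
                           rng_seed = 31415, plates = c("P1", "P2", "P3"),
                           render = FALSE)
  tr <- truth_image_scores(fields) |>
    normalize_plate("siEGFP") |>
    aggregate_treatments()
  samples <- tr[tr$treatment_id != "siEGFP", ]
  expect_lt(mean(samples$is_hit, na.rm = TRUE), 0.05)
})
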