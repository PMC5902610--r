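#' Configuration for the synthetic field-of-view renderer
#'
#' Collects the geometry, intensity and noise parameters of the synthetic
#' three-channel fluorescence renderer. Intensities are on the 12-bit scale
#' (grey values 0 to `pixel_depth`, default 4095). The defaults emulate a
#' PDGF-stimulated fibroblast monolayer imaged at low magnification: adherent
#' cells with dim cytoplasmic actin, bright linear stress fibres, bright
#' annular CDR rings in a fraction of cells, a membrane stain suitable for
#' seeded watershed, and compact nuclei.
#'
#' @param image_shape Integer vector `(height, width)` in pixels.
#' @param pixel_depth Maximum grey value (4095 for 12-bit data).
#' @param baseline_cdr_p Baseline probability that an unperturbed cell forms
#'   a CDR. The screen's readout is linear in this incidence; perturbations
#'   scale it by `1 - cdr_suppression`.
#' @param cell_radius Range (min, max) of cell body radii in pixels. Cells are
#'   placed on a jittered grid so that bodies never overlap.
#' @param nucleus_radius Range of nucleus radii in pixels.
#' @param cdr_inner_radius Range of CDR ring inner radii in pixels.
#' @param cdr_thickness Range of CDR ring thicknesses in pixels.
#' @param cdr_intensity_factor Range of CDR ring intensity as a multiple of
#'   the stress-fibre base intensity.
#' @param fibre_intensity Base stress-fibre grey value; individual fibres
#'   vary around (0.8, 1.2) times this value.
#' @param fibres_per_cell Expected number of stress fibres per cell (Poisson,
#'   plus one guaranteed fibre).
#' @param cytoplasm_intensity Mean cytoplasmic actin grey value.
#' @param membrane_intensity Mean cell-body grey value in the membrane
#'   channel; the outer rim is brighter by `membrane_rim_factor`.
#' @param membrane_rim_factor Multiplier for the membrane rim.
#' @param nucleus_intensity Range of nucleus peak grey values.
#' @param background Named numeric: background grey value per channel
#'   (`actin`, `membrane`, `nucleus`).
#' @param nucleus_speckle Chromatin texture: multiplicative speckle standard
#'   deviation (fraction of local intensity) inside nuclei, drawn before the
#'   optical blur so defocus removes it.
#' @param nucleus_mottle Structured background of the nucleus channel
#'   (autofluorescence/debris mottle): `c(mean, sd)` grey values of a
#'   non-negative per-pixel field added before the optical blur.
#' @param psf_sigma In-focus optical blur (Gaussian sigma, px) applied to all
#'   channels before noise; models the microscope point-spread function.
#' @param poisson_gain Camera gain for signal-dependent shot noise: a pixel of
#'   expected intensity I is drawn as `gain * Poisson(I / gain)`.
#' @param read_noise_sd Additive Gaussian read noise (grey values).
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_shape = c(512L, 512L),
                         pixel_depth = 4095,
                         baseline_cdr_p = 0.6,
                         cell_radius = c(34, 40),
                         nucleus_radius = c(11, 15),
                         cdr_inner_radius = c(5, 12),
                         cdr_thickness = c(2, 5),
                         cdr_intensity_factor = c(1.5, 3),
                         fibre_intensity = 800,
                         fibres_per_cell = 3,
                         cytoplasm_intensity = 280,
                         membrane_intensity = 1150,
                         membrane_rim_factor = 1.5,
                         nucleus_intensity = c(1800, 2600),
                         background = c(actin = 100, membrane = 120, nucleus = 80),
                         nucleus_speckle = 0.5,
                         nucleus_mottle = c(80, 80),
                         psf_sigma = 0.5,
                         poisson_gain = 2,
                         read_noise_sd = 10) {
  if (length(image_shape) != 2L || any(image_shape < 1)) {
    abort("`image_shape` must be two positive integers (height, width).")
  }
  if (pixel_depth <= 0) abort("`pixel_depth` must be positive.")
  if (baseline_cdr_p < 0 || baseline_cdr_p > 1) {
    abort("`baseline_cdr_p` must lie in [0, 1].")
  }
  structure(list(
    image_shape = as.integer(image_shape), pixel_depth = pixel_depth,
    baseline_cdr_p = baseline_cdr_p, cell_radius = cell_radius,
    nucleus_radius = nucleus_radius, cdr_inner_radius = cdr_inner_radius,
    cdr_thickness = cdr_thickness, cdr_intensity_factor = cdr_intensity_factor,
    fibre_intensity = fibre_intensity, fibres_per_cell = fibres_per_cell,
    cytoplasm_intensity = cytoplasm_intensity,
    membrane_intensity = membrane_intensity,
    membrane_rim_factor = membrane_rim_factor,
    nucleus_intensity = nucleus_intensity, background = background,
    nucleus_speckle = nucleus_speckle, nucleus_mottle = nucleus_mottle,
    psf_sigma = psf_sigma, poisson_gain = poisson_gain,
    read_noise_sd = read_noise_sd
  ), class = "synth_config")
}

#' Describe one well of a screening plate
#'
#' A well specification is one row of a plate layout: the treatment applied
#' to the well and the ground-truth effect size the generator should apply.
#'
#' @param well Well identifier, e.g. `"A01"`.
#' @param treatment_id siRNA (or other treatment) identifier.
#' @param gene Target gene symbol.
#' @param role One of `"negative_control"`, `"positive_control"`, `"sample"`.
#' @param cdr_suppression Fraction in `[0, 1]` by which the baseline CDR
#'   incidence is reduced in this well (0 = control-like, 1 = full abolition).
#' @param n_cells_mean Expected number of cells per field.
#' @param defocus_sigma Defocus blur scale in pixels (0 = in focus).
#' @param saturate_fraction Fraction of cells given a saturated actin patch
#'   (> 500 pixels at the maximum grey value).
#'
#' @return A one-row tibble.
#' @export
well_spec <- function(well, treatment_id, gene = treatment_id,
                      role = c("sample", "negative_control", "positive_control"),
                      cdr_suppression = 0, n_cells_mean = 24,
                      defocus_sigma = 0, saturate_fraction = 0) {
  role <- match.arg(role)
  if (cdr_suppression < 0 || cdr_suppression > 1) {
    abort("`cdr_suppression` must lie in [0, 1].")
  }
  if (n_cells_mean < 0) abort("`n_cells_mean` must be non-negative.")
  if (defocus_sigma < 0) abort("`defocus_sigma` must be non-negative.")
  tibble::tibble(
    well = as.character(well), treatment_id = as.character(treatment_id),
    gene = as.character(gene), role = role,
    cdr_suppression = cdr_suppression, n_cells_mean = n_cells_mean,
    defocus_sigma = defocus_sigma, saturate_fraction = saturate_fraction
  )
}

validate_layout <- function(layout, require_negative_control = TRUE) {
  needed <- c("well", "treatment_id", "gene", "role", "cdr_suppression",
              "n_cells_mean", "defocus_sigma", "saturate_fraction")
  missing <- setdiff(needed, names(layout))
  if (length(missing)) {
    abort(paste0("Layout is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(layout$well)) abort("Duplicate well ids in layout.")
  bad <- !layout$role %in% c("negative_control", "positive_control", "sample")
  if (any(bad)) abort("Layout `role` must be negative_control/positive_control/sample.")
  if (any(layout$cdr_suppression < 0 | layout$cdr_suppression > 1)) {
    abort("`cdr_suppression` must lie in [0, 1].")
  }
  if (require_negative_control && !any(layout$role == "negative_control")) {
    abort("Plate layout contains no negative_control well.")
  }
  invisible(layout)
}

# Geometry of one field: non-overlapping elliptical cells on a jittered grid,
# one nucleus per cell, optional CDR ring per cell. All coordinates are
# 0-based (row, col) pixel indices.
sample_field_geometry <- function(well, cfg) {
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  rmax <- cfg$cell_radius[2]
  pitch <- ceiling(2 * rmax * 1.05 + 18)   # guarantees non-overlap with jitter
  jit <- 8
  gr <- seq(pitch / 2, h - pitch / 2, by = pitch)
  gc <- seq(pitch / 2, w - pitch / 2, by = pitch)
  sites <- expand.grid(r = gr, c = gc)
  n_sites <- nrow(sites)
  n <- min(rpois(1, well$n_cells_mean), n_sites)
  if (n <= 0) return(NULL)
  pick <- sample.int(n_sites, n)
  cells <- lapply(seq_len(n), function(k) {
    ctr <- c(sites$r[pick[k]], sites$c[pick[k]]) + runif(2, -jit, jit)
    r <- runif(1, cfg$cell_radius[1], cfg$cell_radius[2])
    ecc <- runif(1, 0.95, 1.05)
    theta <- runif(1, 0, pi)
    nuc_r <- runif(1, cfg$nucleus_radius[1], cfg$nucleus_radius[2])
    nuc_ctr <- ctr + runif(2, -5, 5)
    has_cdr <- runif(1) < cfg$baseline_cdr_p * (1 - well$cdr_suppression)
    cdr <- NULL
    if (has_cdr) {
      ri <- runif(1, cfg$cdr_inner_radius[1], cfg$cdr_inner_radius[2])
      th <- runif(1, cfg$cdr_thickness[1], cfg$cdr_thickness[2])
      off_r <- runif(1, 0, 0.3 * r)
      off_a <- runif(1, 0, 2 * pi)
      cdr <- list(ctr = ctr + off_r * c(cos(off_a), sin(off_a)),
                  inner = ri, thickness = th,
                  intensity = cfg$fibre_intensity *
                    runif(1, cfg$cdr_intensity_factor[1], cfg$cdr_intensity_factor[2]))
    }
    n_fib <- 1L + rpois(1, cfg$fibres_per_cell - 1)
    fibres <- lapply(seq_len(n_fib), function(f) {
      list(angle = runif(1, 0, pi), offset = runif(1, -0.6 * r, 0.6 * r),
           width = runif(1, 1.0, 1.7),
           intensity = cfg$fibre_intensity * runif(1, 0.8, 1.2))
    })
    saturate <- runif(1) < well$saturate_fraction
    list(ctr = ctr, r = r, a = r * ecc, b = r / ecc, theta = theta,
         nuc_ctr = nuc_ctr, nuc_r = nuc_r, cdr = cdr, fibres = fibres,
         cyto = cfg$cytoplasm_intensity + runif(1, -40, 60),
         memb = cfg$membrane_intensity + runif(1, -80, 80),
         nuc_int = runif(1, cfg$nucleus_intensity[1], cfg$nucleus_intensity[2]),
         saturate = saturate)
  })
  cells
}

# Paint helper: returns local window coordinates and elliptical radial
# coordinate (1 at the cell outline) for a cell within the image bounds.
cell_window <- function(cell, h, w, pad = 2) {
  ext <- max(cell$a, cell$b) + pad
  r0 <- max(0, floor(cell$ctr[1] - ext)); r1 <- min(h - 1, ceiling(cell$ctr[1] + ext))
  c0 <- max(0, floor(cell$ctr[2] - ext)); c1 <- min(w - 1, ceiling(cell$ctr[2] + ext))
  rr <- r0:r1; cc <- c0:c1
  dy <- rr - cell$ctr[1]; dx <- cc - cell$ctr[2]
  DY <- matrix(dy, length(rr), length(cc))
  DX <- matrix(dx, length(rr), length(cc), byrow = TRUE)
  u <- DY * cos(cell$theta) + DX * sin(cell$theta)
  v <- -DY * sin(cell$theta) + DX * cos(cell$theta)
  rho <- sqrt((u / cell$a)^2 + (v / cell$b)^2)
  list(rows = rr + 1L, cols = cc + 1L, rho = rho, DY = DY, DX = DX, u = u, v = v)
}

#' Render one synthetic field of view with ground truth
#'
#' Draws the three channels (actin/phalloidin, membrane, nucleus) for one
#' field of one well and returns them together with the geometric ground
#' truth (cell and nucleus label maps, CDR mask, per-cell CDR pixel counts).
#' Ground truth reflects the geometry before optical blur and noise.
#'
#' Rendering order: geometry is painted at nominal intensity, the point-spread
#' blur and any defocus blur are applied, then Poisson-Gaussian noise, then
#' clipping to `[0, pixel_depth]` and rounding to integer grey values; finally
#' saturated sensor patches are stamped for cells flagged by
#' `saturate_fraction`.
#'
#' @param well A one-row layout tibble (see [well_spec()]).
#' @param field_index Field number within the well (1-based).
#' @param cfg A [synth_config()].
#' @param rng_seed Integer seed; every random draw derives from it.
#' @param plate Plate identifier used in the per-field seed derivation, so
#'   replicate plates differ.
#' @param render If `FALSE`, skip channel rendering and return ground truth
#'   only (fast path for scoring-level simulations).
#'
#' @return A list with elements `images` (list of `actin`, `membrane`,
#'   `nucleus` matrices, or `NULL` when `render = FALSE`), `truth` (list with
#'   `cell_labels`, `nucleus_labels`, `cdr_mask`, `per_cell_cdr_pixels`,
#'   `cdr_positive`), and `meta` (plate/well/field identity).
#' @export
render_image_set <- function(well, field_index, cfg = synth_config(),
                             rng_seed, plate = "P1", render = TRUE) {
  if (missing(rng_seed) || is.null(rng_seed)) {
    abort("`rng_seed` is required for deterministic rendering.")
  }
  if (!inherits(cfg, "synth_config")) abort("`cfg` must be a `synth_config`.")
  if (is.data.frame(well)) {
    if (nrow(well) != 1L) abort("`well` must be a single layout row.")
    well <- as.list(well)
  }
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  field_seed <- stable_hash(rng_seed, plate, well$well, field_index)

  with_seed(field_seed, {
    cells <- sample_field_geometry(well, cfg)

    cell_labels <- matrix(0L, h, w)
    nucleus_labels <- matrix(0L, h, w)
    cdr_mask <- matrix(FALSE, h, w)
    actin <- membrane <- nucleus <- NULL
    if (render) {
      actin <- matrix(cfg$background[["actin"]], h, w)
      membrane <- matrix(cfg$background[["membrane"]], h, w)
      nucleus <- matrix(cfg$background[["nucleus"]], h, w)
    }

    n_cells <- length(cells)
    cdr_positive <- logical(n_cells)
    sat_cells <- integer(0)

    for (k in seq_len(n_cells)) {
      cell <- cells[[k]]
      cw <- cell_window(cell, h, w)
      inside <- cw$rho <= 1
      sub <- cbind(rep(cw$rows, ncol(inside))[inside],
                   rep(cw$cols, each = nrow(inside))[inside])
      cell_labels[sub] <- k

      # nucleus blob
      dyn <- (cw$rows - 1L) - cell$nuc_ctr[1]
      dxn <- (cw$cols - 1L) - cell$nuc_ctr[2]
      DN <- sqrt(outer(dyn^2, dxn^2, `+`))
      nuc_in <- DN <= cell$nuc_r & inside
      subn <- cbind(rep(cw$rows, ncol(nuc_in))[nuc_in],
                    rep(cw$cols, each = nrow(nuc_in))[nuc_in])
      nucleus_labels[subn] <- k

      # CDR annulus
      if (!is.null(cell$cdr)) {
        dyc <- (cw$rows - 1L) - cell$cdr$ctr[1]
        dxc <- (cw$cols - 1L) - cell$cdr$ctr[2]
        DC <- sqrt(outer(dyc^2, dxc^2, `+`))
        ring <- DC >= cell$cdr$inner & DC <= (cell$cdr$inner + cell$cdr$thickness) &
          inside
        if (any(ring)) {
          subr <- cbind(rep(cw$rows, ncol(ring))[ring],
                        rep(cw$cols, each = nrow(ring))[ring])
          cdr_mask[subr] <- TRUE
          cdr_positive[k] <- TRUE
        }
      }

      if (render) {
        # membrane: body plus bright rim
        memb_val <- matrix(0, nrow(inside), ncol(inside))
        memb_val[inside] <- cell$memb
        rim <- inside & cw$rho >= 0.92
        memb_val[rim] <- cell$memb * cfg$membrane_rim_factor
        membrane[cw$rows, cw$cols] <- pmax(membrane[cw$rows, cw$cols], memb_val)

        # nucleus channel: smooth blob with radial falloff
        nuc_val <- matrix(0, nrow(inside), ncol(inside))
        nuc_val[nuc_in] <- cell$nuc_int * (1 - 0.3 * (DN[nuc_in] / cell$nuc_r)^2)
        nucleus[cw$rows, cw$cols] <- pmax(nucleus[cw$rows, cw$cols], nuc_val)

        # actin: dim cytoplasm, linear fibres, CDR ring on top
        act_val <- matrix(0, nrow(inside), ncol(inside))
        act_val[inside] <- cell$cyto
        for (f in cell$fibres) {
          d_line <- abs(cw$u * cos(f$angle) + cw$v * sin(f$angle) - f$offset)
          fib <- inside & d_line <= f$width & cw$rho <= 0.95
          act_val[fib] <- pmax(act_val[fib], f$intensity)
        }
        if (!is.null(cell$cdr)) {
          dyc <- (cw$rows - 1L) - cell$cdr$ctr[1]
          dxc <- (cw$cols - 1L) - cell$cdr$ctr[2]
          DC <- sqrt(outer(dyc^2, dxc^2, `+`))
          ring <- DC >= cell$cdr$inner & DC <= (cell$cdr$inner + cell$cdr$thickness) &
            inside
          act_val[ring] <- cell$cdr$intensity
        }
        actin[cw$rows, cw$cols] <- pmax(actin[cw$rows, cw$cols], act_val)
        if (cell$saturate) sat_cells <- c(sat_cells, k)
      }
    }

    per_cell <- integer(n_cells)
    if (n_cells > 0) {
      tab <- tabulate(cell_labels[cdr_mask], nbins = n_cells)
      per_cell <- as.integer(tab)
      names(per_cell) <- as.character(seq_len(n_cells))
      names(cdr_positive) <- as.character(seq_len(n_cells))
    }

    images <- NULL
    if (render) {
      # fine pre-optics structure of the DNA channel: chromatin speckle and
      # background mottle; gives in-focus fields the high-frequency power the
      # focus metric relies on, and defocus removes it
      if (cfg$nucleus_speckle > 0) {
        nucleus <- nucleus *
          (1 + cfg$nucleus_speckle * matrix(rnorm(h * w), h, w) *
             (nucleus_labels > 0L))
      }
      if (cfg$nucleus_mottle[2] > 0 || cfg$nucleus_mottle[1] > 0) {
        nucleus <- nucleus +
          matrix(pmax(rnorm(h * w, cfg$nucleus_mottle[1],
                            cfg$nucleus_mottle[2]), 0), h, w)
      }
      blur_sigma <- sqrt(cfg$psf_sigma^2 + well$defocus_sigma^2)
      chans <- list(actin = actin, membrane = membrane, nucleus = nucleus)
      chans <- lapply(chans, function(ch) {
        ch <- gauss_smooth(ch, blur_sigma)
        g <- cfg$poisson_gain
        ch <- g * rpois(length(ch), pmax(ch, 0) / g) +
          rnorm(length(ch), 0, cfg$read_noise_sd)
        matrix(round(clamp(ch, 0, cfg$pixel_depth)), h, w)
      })
      # sensor saturation patches (post-noise, as clipping is a sensor property)
      for (k in sat_cells) {
        cell <- cells[[k]]
        ctr <- cell$ctr + runif(2, -6, 6)
        rad <- 14
        r0 <- max(1, floor(ctr[1] - rad)); r1 <- min(h, ceiling(ctr[1] + rad))
        c0 <- max(1, floor(ctr[2] - rad)); c1 <- min(w, ceiling(ctr[2] + rad))
        rr <- r0:r1; cc <- c0:c1
        D <- sqrt(outer((rr - 1 - ctr[1])^2, (cc - 1 - ctr[2])^2, `+`))
        patch <- chans$actin[rr, cc]
        patch[D <= rad] <- cfg$pixel_depth
        chans$actin[rr, cc] <- patch
      }
      images <- chans
    }

    list(
      images = images,
      truth = list(cell_labels = cell_labels, nucleus_labels = nucleus_labels,
                   cdr_mask = cdr_mask, per_cell_cdr_pixels = per_cell,
                   cdr_positive = cdr_positive),
      meta = tibble::tibble(plate = plate, well_id = well$well,
                            field = as.integer(field_index),
                            treatment_id = well$treatment_id, gene = well$gene,
                            role = well$role) |>
        dplyr::rename(well = "well_id")
    )
  })
}

#' Generate all fields of a plate (or replicate plates)
#'
#' @param layout Plate layout tibble; one row per well (see [well_spec()]).
#' @param fields_per_well Number of fields imaged per well.
#' @param cfg A [synth_config()].
#' @param rng_seed Master seed; per-field seeds are derived from it with a
#'   stable hash of (seed, plate, well, field), so fields are independent and
#'   reproducible.
#' @param plates Character vector of plate identifiers; each plate is an
#'   independent replicate of the layout.
#' @param render If `FALSE`, generate ground truth only.
#'
#' @return A tibble with one row per field: identity columns plus list
#'   columns `images` and `truth` as returned by [render_image_set()].
#' @export
generate_plate <- function(layout, fields_per_well = 9, cfg = synth_config(),
                           rng_seed, plates = "P1", render = TRUE) {
  validate_layout(layout)
  if (fields_per_well < 1) abort("`fields_per_well` must be >= 1.")
  if (missing(rng_seed)) abort("`rng_seed` is required.")
  grid <- tidyr::expand_grid(plate = plates, wi = seq_len(nrow(layout)),
                             field = seq_len(fields_per_well))
  out <- purrr::pmap(grid, function(plate, wi, field) {
    fs <- render_image_set(layout[wi, ], field, cfg, rng_seed = rng_seed,
                           plate = plate, render = render)
    dplyr::mutate(fs$meta, images = list(fs$images), truth = list(fs$truth))
  })
  dplyr::bind_rows(out)
}
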