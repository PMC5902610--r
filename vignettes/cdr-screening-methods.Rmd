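---
title: "Methods: scoring circular dorsal ruffle formation in image-based RNAi screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring circular dorsal ruffle formation in image-based RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cdrscreen)
```

## The assay and the readout

Circular dorsal ruffles (CDRs) are transient, ring-shaped, actin-rich
protrusions that fibroblasts form on their apical surface within minutes of
growth-factor (PDGF) stimulation. Because most stimulated cells form a single
prominent CDR in a narrow time window, the fraction of CDR-forming cells — or
equivalently the amount of CDR-classified actin signal per cell — is a
sensitive, quantitative phenotype for RNAi perturbation screens: an siRNA
that blocks CDR formation identifies a candidate regulator.

cdrscreen implements the complete analysis that turns raw three-channel
fluorescence images (actin/phalloidin, plasma-membrane stain, DNA stain) of a
96-well plate into per-siRNA *CDR scores* and validated gene hits:

1. **Nucleus segmentation** (DNA channel): robust-background threshold, hole
   filling, 8-connected labeling, minimum size 50 px.
2. **Focus QC**: the slope of the log-log radially averaged power spectrum of
   the DNA channel; images with slope below −2 are discarded as out of focus.
3. **Cell segmentation** (membrane channel): seeded watershed on the
   smoothed, background-corrected image, nuclei as seeds.
4. **Cell shrinking and filters**: each cell is eroded by 5 px to exclude
   boundary pixels, then kept only if its area is ≥ 2500 px, its mean actin
   grey value is ≥ 200 (12-bit scale, maximum 4095), and it contains at most
   500 saturated actin pixels. All three rejection rules are strict as
   printed; equality keeps the cell.
5. **CDR pixel classification** (actin channel): a supervised two-class
   pixel classifier (CDR vs background, where background includes stress
   fibres and cytoplasm) produces a per-pixel probability image.
6. **CDR objects**: probability ≥ 0.51, morphological closing with a
   7-px-diameter disk, 8-connected components, minimum object area 25 px.
7. **Scoring**: per image, the mean CDR pixel count over kept cells (the raw
   score); per plate, division by the mean raw score of the QC-passing
   negative-control (siEGFP) images (the ratio score); per siRNA, the mean
   ratio score over all QC-passing images (the CDR score). An siRNA with CDR
   score < 0.4 (i.e. more than 60% reduction relative to control) is a hit;
   a gene is validated when at least 2 of its 3 siRNAs are hits.

A kinematics module implements the quantification formulas used downstream
of the screen: chemotaxis track metrics (velocity; directionality =
Euclidean/travelled distance; forward migration index), protrusion
orientation angles, corrected total cell fluorescence
(CTCF = integrated density − area × mean background), oscillation-period
estimation for recurrent CDR waves, and line-ROI kymographs.

## The synthetic plate generator

No imaging data accompany the screen, so the package ships a ground-truth
generator that emulates the statistical structure the pipeline relies on,
making every stage testable end to end. Each field draws non-overlapping
elliptical cells on a jittered grid (guaranteeing ground-truth label maps),
one nucleus per cell, linear stress fibres, and — with probability
`baseline_cdr_p × (1 − cdr_suppression)` per cell — one annular CDR. The
three channels are painted at nominal intensity, blurred by the optical
point-spread function (plus any defocus), degraded with Poisson shot noise
and Gaussian read noise, clipped to the 12-bit range, and rounded.

Key defaults, chosen once as the package's study conditions:

* `image_shape = 512 × 512` px, ~24 cells per field. Fields are smaller than
  a real screening camera frame; cell-scale geometry (radius 34–40 px,
  nuclei 11–15 px) matches low-magnification imaging so that the screen's
  printed pixel thresholds (2500 px cells, 25 px CDR objects) are meaningful
  unchanged.
* `baseline_cdr_p = 0.6`: the fraction of unperturbed, stimulated cells that
  form a CDR. In PDGF-stimulated fibroblast populations the majority of
  cells form CDRs but the exact fraction varies between preparations, so the
  generator exposes it as a parameter; the default 0.6 keeps both classes
  (CDR-positive and negative cells) well represented for validation, and the
  readout is linear in this incidence, so it cancels in the ratio score.
* CDR rings: inner radius 5–12 px, thickness 2–5 px, intensity 1.5–3× the
  stress-fibre level — bright enough to be learnable, overlapping the fibre
  intensity range enough that texture (curvature) features matter.
* Noise: Poisson gain 2 plus read noise sd 10 grey values, a standard
  fluorescence-camera model.
* The DNA channel additionally carries pre-optics fine structure — chromatin
  speckle inside nuclei and a background mottle field — drawn *before* the
  blur. This is what gives an in-focus image its high-frequency spectral
  power (slope ≈ −1.7, passing the −2 QC cut) while defocus removes it
  (slope < −2 for defocus σ around 1–3 px).

What the generator does **not** emulate: touching or overlapping cells (so
no declumping is exercised), illumination gradients beyond a Gaussian
background, intracellular actin texture beyond discrete fibres, partial or
broken CDR rings, and 3D/z effects. Passing tests therefore demonstrate the
pipeline's correctness and its behaviour under the modelled noise, not
performance on all real-data pathologies.

## Numerical and design choices

* **Robust background threshold**: discard the dimmest and brightest 5% of
  pixels, then mean + 2 sd, clipped to [0, 4095]. These are the
  conventional defaults of the robust-background rule; both trims and the
  sd multiplier are arguments.
* **Membrane foreground mask**: the same estimator with upper trim raised to
  0.35 (argument `mask_upper_trim`). With adherent cells covering 30–40% of
  the field, a 5% trim leaves most foreground pixels in the "background"
  population and the resulting threshold lands above the cell interior; a
  trim larger than the foreground fraction restores the intended behaviour.
* **Seeded watershed**: Meyer-style priority flooding of the inverted
  smoothed membrane image, implemented in C++ with ties broken by insertion
  (scan) order, so results are bit-reproducible. Seeds keep their nucleus
  labels; a seed with no surrounding foreground yields a cell equal to its
  own footprint.
* **Focus metric**: radially averaged power spectral density in unit-width
  frequency annuli, least-squares line on log10 power vs log10 frequency
  over 0.05–0.45 cycles/px (excludes DC and the aliasing corner; band is an
  argument). Constant images return `NA` with a warning and are treated as
  out of focus by QC. Known limitation: with blur applied before sensor
  noise, an *extremely* defocused field (σ ≈ 8 px) is noise-dominated and
  its spectrum flattens towards slope 0 — the metric, like its
  high-content-screening ancestors, detects moderate defocus, not
  arbitrarily severe blur.
* **Shrinking**: per-object Euclidean erosion via the distance transform
  (pixels farther than `n_px` from the object's complement); objects that
  vanish are dropped. Composition of erosions agrees with a single erosion
  to within ~2–3% rasterization differences.
* **Pixel classifier**: five features per scale (smoothed intensity,
  gradient magnitude, Laplacian, both Hessian eigenvalues) at scales 0.7,
  1.6, 3.5, 5.0 px — the conventional minimal set for ring/texture
  discrimination. The classifier is a seeded random forest of 100 bagged
  regression trees on the class indicator with unshrunk leaves, so
  predictions are vote fractions in [0, 1]; it is trained and evaluated with
  the xgboost engine (`num_parallel_tree`), whose single-threaded per-pixel
  prediction is orders of magnitude faster than classical random-forest
  implementations at identical ensemble semantics. Training labels for
  synthetic data are derived automatically from ground truth (CDR mask
  dilated by 1 px vs sampled background, half uniform, half
  intensity-weighted so bright fibres are represented); sparse manual label
  images (0/1/2) are supported unchanged.
* **Thresholds**: the 0.51 probability cut is inclusive (≥) — the exact
  value is uncritical because the ratio score normalizes it out — and the
  0.4 hit threshold is strict (<), as are all rejection boundaries.
* **Aggregation**: ratio scores are pooled per image across replicate plates
  (each QC-passing image counts once); `pooling = "per_plate"` averages
  plate means instead. Positive-control wells are not excluded from
  ranking; both choices are arguments.
* **Oscillation detector**: peaks are local maxima with topographic
  prominence ≥ 0.25 of the trace's dynamic range and ≥ 4 samples apart,
  after a centred 3-sample moving average (`smooth_window`, set 1 to
  disable) that suppresses single-sample noise maxima without shifting
  symmetric peaks; the period is the mean inter-peak interval. The relative
  prominence makes the estimate invariant to affine intensity rescaling.
* **Track metrics**: the forward migration index divides the displacement
  along the gradient by the *travelled* path length (the chemotaxis-tool
  convention); `fmi_denominator = "euclidean"` selects the variant.
  Protrusion angles are reported unfolded in [0, 180°] by default, with
  `fold = TRUE` mapping to [0, 90°] — both conventions appear in the
  literature for "alignment with the gradient".
* **Determinism**: every stochastic step takes a seed; per-field seeds
  derive from the master seed by a stable 31-bit polynomial hash of
  (seed, plate, well, field), so fields are independent, reproducible and
  insensitive to generation order.

## Problem sizes used in validation

The package's own validation (tests and the acceptance script) uses 512×512
fields with ~24 cells: recognition quality is measured by training on 10
fields and evaluating ~900 held-out cells on 40 fields; the simulated screen
uses 4 wells × 9 fields × 3 replicate plates through the full image
pipeline; scoring-level properties (effect recovery, null behaviour) use the
generator's ground-truth fast path (`render = FALSE`) over 5 seeds at 6–21
wells. These sizes were chosen so a complete validation runs on a laptop
CPU; all of them are arguments to the corresponding functions.

Under these conditions the held-out cell-level recognition reaches a
true-positive rate near 1.0 and a false-positive rate near 0.01–0.02, and a
treatment whose ground-truth CDR incidence is 30% of control scores ≈ 0.3,
cleanly below the 0.4 hit threshold, while null treatments score 1.0 ± 0.1.

## Known limitations

* Synthetic cells never touch, so watershed boundary placement between
  contacting cells and nucleus declumping are untested against ground truth.
* Per-siRNA score variability under the default conditions (24 cells/field,
  9 fields × 3 plates, CDR ring areas spanning ~75–450 px) has sd ≈ 0.05;
  screens needing tighter scores should raise fields per well or replicate
  plates.
* The focus metric's extreme-blur failure mode described above.
* The classifier is trained per screen (or per generator configuration);
  a classifier trained at one intensity regime does not transfer to images
  with very different staining levels without retraining.
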