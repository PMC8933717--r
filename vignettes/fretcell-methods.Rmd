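---
title: "Methods: single-cell FRET quantification with fretcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell FRET quantification with fretcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretcell)
```

## The measurement problem

Genetically encoded FRET biosensors report an intracellular analyte (here,
cytosolic glucose) as the ratio of sensitized acceptor emission to donor
emission. Recording that ratio per *cell* in a dense, heterogeneous field —
for example differentiated 3T3-L1 adipocytes after insulin stimulation —
requires three things that fretcell provides headlessly:

1. **Segmentation** of round, low-contrast cells in the transmitted-light
   (brightfield) channel, starting from a rough per-cell seed;
2. **Quantification** of per-cell mean intensities over four channels and
   time, reduced to a normalized FRET-ratio trace per cell;
3. **Population analysis**: exponential uptake kinetics per cell, and
   statistics that relate response magnitude to cell size.

Input stacks are xyct (multi-page TIFF; one file, or one file per
timepoint), with channels held internally in the canonical order
brightfield, donor, acceptor (donor-excited, i.e. sensitized emission),
direct acceptor. Pixel coordinates in all seed/click files are 0-based,
`(x, y)` = (column, row), origin top-left. Data digitised to 12 bits are
stored in 16-bit containers on disk; `bit_depth` is metadata and a
validation bound, not re-quantisation.

## Segmentation

### Seeded active contour

Each seed is an ellipse (centre, horizontal/vertical radii) standing in for
the interactive click-and-adjust step of a GUI. The rasterized ellipse is
refined by a *greedy polar snake*: the contour is parameterised as radii
`r(theta)` at 72 control angles around the seed centroid, and each
iteration every control point moves within a +/-3 px radial window to
minimise

\[
E_i = -\,\tilde g(x_i, y_i) \; + \; \alpha\,(r_i - \bar r_i)^2
      \; + \; \gamma\,|\Delta r_i| \; - \; \beta\,\Delta r_i ,
\]

where `g~` is the locally normalised, Gaussian-smoothed gradient magnitude
of the brightfield frame (smoothing sigma 2 px before the gradient, 3 px
after it to widen each edge's attraction basin), `r-bar` is the mean of the
two neighbouring radii (curvature penalty, `alpha = 0.02` per px^2),
`gamma = 0.003` discourages drift on flat energy, and `beta` is an optional
balloon pressure (0 by default: the contour deforms only toward contours).
The design follows the classical snake idea — a deformable closed curve
descending an image-energy landscape — in the discrete greedy form, which
is robust on noisy, low-contrast membranes and cannot self-intersect
because the contour stays star-convex.

Two contractual properties matter more than the particular energy:

* `n_iterations` **hard-caps deformation** (at most 3 px radially per
  iteration); `n_iterations = 0` returns the initial mask unchanged. Ten
  iterations is the default and is what routinely locates adipocyte
  boundaries.
* The output is always **one 8-connected component**; if the filled contour
  fragments, the largest component is kept, and a collapse to zero pixels
  is an error naming the cell.

Masks from different seeds are made pairwise disjoint by assigning
contested pixels to the nearest seed centre (ties to the lower cell id).
Segmentation runs once on the brightfield frame at t = 0 and the masks are
reused at all timepoints; the cells studied here are stationary over a
30-min recording, and tracking is out of scope.

### Threshold + click-seeded watershed

For spread, fluorescent cell types the alternative path thresholds a
fluorescence channel (inclusive `>=`, hole filling, minimum component area
50 px), then splits each clicked connected component by distance: every
pixel joins the basin of the nearest click, ridge ties go to the lower cell
id, and clicks that collapse into another basin produce a warning. The
union of the returned masks is exactly the set of clicked components.

### Size measure and validation

Cell size is the **area-equivalent diameter** `2*sqrt(A/pi)*pixel_size`,
the standard measure for near-round cells (exact on discs). Agreement with
reference masks is scored by the Jaccard coefficient
`|A intersect B| / |A union B|`.

## Quantification and kinetics

The raw FRET ratio is the mean sensitized-acceptor intensity over the mean
donor intensity inside the mask (no bleed-through correction; the direct
acceptor channel is carried as an expression covariate only, since FRET
requires donor excitation). Traces are normalized by their first value, so
every cell starts at 1; the **total relative change** is final minus first
value — positive for stimulated uptake. No background subtraction is
applied by default.

The relative-change trace `dF(t) = F_norm(t) - 1` is fitted with

\[
dF(t) = F_{final}\,\bigl(1 - e^{-k_u t}\bigr),
\]

by bounded Levenberg–Marquardt least squares (`F_final` in (-1, 5), `k_u`
in [0, 10] per min, parameter tolerance 1e-8; start values: last relative
change, and 1/duration). Fitting `dF` rather than `F_norm` matches the
model's `F(0) = 0` while traces start at 1; the convention is isolated in
`fit_uptake()`. Fits with `R^2` *strictly below* 0.8 — or non-converged, or
on constant traces where `R^2` is undefined — are discarded;
`R^2 = 0.80` exactly is kept.

**Identifiability.** With 7 timepoints over 30 min and `k_u ~ 0.1/min` the
likelihood has a flat ridge along which amplitude and rate trade off, so
under trace noise of sigma ~0.05 single-cell estimates are skewed
(occasional small-`k`, large-`F` fits). The package's Monte-Carlo checks
therefore assert that estimator bias is small relative to the sampling
spread and that the median rate sits on the truth, rather than strict
mean-unbiasedness, which this design cannot deliver at that noise level.
On noiseless traces the fit inverts the model to better than 1e-3.

## Population statistics

* **Size split:** cells below the mean diameter are "small", at or above it
  "large" (ties at the mean go to large).
* **Means** are compared with the two-sided pooled-variance Student's
  t-test, **distributions** with the two-sample Kolmogorov–Smirnov test
  (asymptotic p-values); significance is called at p < 0.05, with no
  multiple-testing correction.
* **Size–response coupling** is the sample Pearson correlation between
  diameter and total relative change, reported with the free linear fit.
* **Densities** are Gaussian KDEs with Silverman's rule-of-thumb bandwidth,
  on a 256-point grid spanning the data range +/- 3 bandwidths.
* Group means are additionally reported normalized to the small group, the
  convention used when comparing small/large basal/stimulated adipocytes.

## The synthetic ground-truth generator

Every quantitative claim the test suite makes is measured against fields
from `generate_population()` + `render_timelapse()`, which emulate the
target imaging regime:

* **Geometry:** 768 x 768 px at 0.42 um/px (a ~320 um field, i.e. a
  2x2-binned crop of a wide-field confocal scan), 30 cells per field by
  default with area-equivalent diameters uniform on 15–45 um (mean ~30 um),
  placed without overlap by rejection sampling at ~20% area coverage —
  a dense field in which neighbouring cells frequently nearly touch. A
  512 px field at the native 0.21 um/px cannot hold 30 such cells (their
  summed area exceeds the field), which is why the desk-scale default bins
  rather than crops harder.
* **Brightfield:** flat background (2000 counts) with a ~2.4 px-wide
  membrane ring at 10% contrast straddling each true boundary and random
  +/-5% lipid-droplet blobs inside each cell — the low-contrast texture
  that defeats intensity-only segmentation.
* **Fluorescence:** each cell's total sensor emission `L` (900–1600
  counts) is partitioned as donor `L/(1+rho)` and acceptor `L rho/(1+rho)`
  so the within-cell ratio equals the programmed
  `rho(t) = baseline * (1 + F_final (1 - e^{-k_u t}))` exactly before
  noise; background fluorescence is 60 counts. The direct-acceptor channel
  is constant per cell. This is a phenomenological ratio model, not a
  spectral simulation: the acceptor/donor mean ratio is the only
  contractual quantity.
* **Noise:** Poisson shot noise, then Gaussian read noise (sigma 4 counts
  by default), then rounding and clipping to [0, 4095] (12-bit).
* **Time base:** t = 0, 5, ..., 30 min.
* **Seeding error:** `truth_seeds()` displaces each seed centre by up to
  20% of the cell radius in a random direction — the rough-click regime.

What the generator does **not** emulate: optical PSFs and defocus,
photobleaching, cell movement, spectral bleed-through, and irregular
(non-star-convex) morphologies. Passing benchmarks on these fields
therefore demonstrates correct algorithmic behaviour in the intended
regime, not performance on arbitrary real microscopy.

## Validation benchmarks

`segmentation_benchmark()` scores active-contour masks against truth over
5 fields x 30 cells (offset seeds, 10 iterations) and reports the mean
Jaccard coefficient; with the defaults above the pipeline's agreement is
well clear of 0.76, the level at which automated segmentation matches
manual outlining of adipocytes in practice.

`size_response_benchmark()` is the end-to-end recovery check: each of 5
replicates simulates 140 stimulated cells (spread over 5 fields) whose
programmed response couples to diameter as
`F_final = 0.35 - 0.004 d + N(0, 0.1465)` — a programmed population
correlation of

\[
r = \frac{s\,\sigma_d}{\sqrt{s^2 \sigma_d^2 + \sigma^2}} \approx -0.23
\qquad (\sigma_d = 30/\sqrt{12}),
\]

renders low-read-noise stacks, and runs segmentation, quantification,
normalization and correlation. The recovered mean correlation must land
within the sampling error of r at n = 140 (about +/-0.08).

Both benchmarks derive per-field RNG seeds from a single base seed and are
exactly reproducible. Problem sizes (5 x 30 cells; 5 x 140 cells at 768 px)
were chosen as the smallest populations at which the scores' sampling error
is comfortably below the margins being tested.

## Numerical and design choices

* Threshold comparison is inclusive (`>=`); minimum component area 50 px.
* Watershed ridge ties and overlap contention both resolve to the lower
  cell id, making results independent of input order.
* `EBImage::bwlabel()` (4-connected) is used only inside the threshold
  area filter; all mask invariants use the package's own 8-connected
  labelling.
* KS p-values are asymptotic even at small n, favouring comparability over
  exactness; pooled-variance t rather than Welch, switchable at the call
  site by using `stats::t.test()` directly.
* The fit optimizer is Levenberg–Marquardt with box bounds
  (`minpack.lm::nlsLM`); non-convergence is recorded, not fatal, and such
  cells are excluded by the quality filter.
* Normalization and total-relative-change computation are folded into the
  pipeline (historically often done in a spreadsheet afterwards); this is
  deliberate and logged with all other settings for provenance.

## Known limitations

Star-convex contours cannot follow deeply lobed cells — use the
threshold/watershed path there. Masks are fixed at t = 0, so moving cells
smear their own ratio. The raw ratio is not a corrected FRET efficiency and
should only be compared within an imaging configuration. Uptake-rate
estimates on short traces carry ridge-shaped uncertainty (see
Identifiability) and should be interpreted population-wise, after the
`R^2` filter.
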