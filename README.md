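# fretcell

Single-cell quantification of ratiometric FRET-biosensor signals from
multi-channel time-lapse microscopy, for experiments that ask how a
metabolic response varies *across* cells — for example, whether larger
adipocytes take up less glucose after insulin.

Fields of cultured cells expressing a FRET nanosensor are recorded as xyct
stacks with four channels: brightfield, donor, donor-excited acceptor
(sensitized emission) and direct acceptor. fretcell replaces the
interactive parts of this analysis with files and functions:

* **Seeded segmentation** — each cell starts from a rough seed ellipse (a
  CSV standing in for a GUI click) and is refined by an active contour on
  the brightfield image; or, for spread fluorescent cells, an intensity
  threshold is split into cells by click-seeded distance-transform
  watershedding. Masks report the area-equivalent diameter
  `2*sqrt(A/pi) * pixel size` and can be validated against reference masks
  with the Jaccard (intersection-over-union) score.
* **Trace extraction** — per-cell mean intensity in every channel over
  time; the raw FRET ratio `acceptor / donor`; traces normalized to their
  first value; the total relative change (final − first).
* **Uptake kinetics** — each relative-change trace is fitted with the
  rise-to-plateau model `dF(t) = F_final (1 − exp(−k_u t))` by bounded
  nonlinear least squares; fits with `R² < 0.8` are discarded.
* **Population statistics** — small/large split at the mean diameter,
  pooled-variance t-tests, two-sample Kolmogorov–Smirnov tests (p < 0.05),
  Pearson diameter–response correlation with a free linear fit, and
  Gaussian kernel density estimates.
* **Ground-truthed simulation** — a generator renders dense fields of
  round, low-contrast cells with programmed per-cell FRET dynamics, shot +
  read noise and 12-bit digitisation, so every stage is testable without
  microscopy data.

## Worked example

Simulate a stimulated field whose response amplitude is programmed to fall
with diameter (slope −0.004 per µm, noise σ = 0.1465 — a programmed
population correlation of −0.23), then run the full pipeline:

```r
library(fretcell)

sim <- simulate_field("demo", n_cells = 20, rng_seed = 42,
                      shape = c(640, 640),
                      coupling = list(intercept = 0.35, slope = -0.004,
                                      sigma = 0.1465))
res <- run_pipeline(run_config(input = "demo/stack.tif",
                               seeds = "demo/seeds.csv",
                               out_dir = "demo_out"))
res$counts
#>    cells_segmented             traces skipped_degenerate          fits_kept
#>                 20                 20                  0                 20
#>     fits_discarded
#>                  0

head(res$records, 4)
#>   cell_id diameter_um total_relative_change f_final k_u_per_min r_squared kept
#> 1       1        42.4                0.2863  0.2856       0.208     1.000 TRUE
#> 2       2        42.9                0.0258  0.0257       0.226     0.997 TRUE
#> 3       3        23.2                0.2458  0.2454       0.235     1.000 TRUE
#> 4       4        39.8                0.2807  0.2806       0.222     1.000 TRUE

res$stats$correlation$r
#> [1] -0.262
res$stats$groups
#>   group  n  mean     se mean_normalized
#> 1 small  9 0.225 0.0313           1.000
#> 2 large 11 0.194 0.0396           0.864
```

All 20 cells segment and fit cleanly (`r_squared` ≈ 1 at this noise
level); the recovered diameter–response correlation (−0.262) sits on the
programmed −0.23 within the sampling error of n = 20; and the
mean response of large cells is 86% of the small-cell mean in this draw.
`demo_out/` also receives `traces.csv`, `fits.csv`, the two stats CSVs, a
labelled boundary-overlay PNG, a 16-bit label TIFF and a run log recording
every setting.

The same pipeline runs from a shell:

```sh
inst/cli/fretcell simulate --out demo --cells 20 --seed 42
inst/cli/fretcell run --input demo/stack.tif --seeds demo/seeds.csv --out demo_out
```

Real data enter through `load_stack()` (multi-page TIFF or a list of
per-timepoint files; OME-TIFF axis metadata is honoured) and a seed CSV
with columns `cell_id, x, y, radius_x[, radius_y]` in 0-based pixel
coordinates.

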