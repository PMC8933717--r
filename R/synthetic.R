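# Ground-truthed synthetic imagery. Emulates confocal fields of round,
# low-contrast adipocyte-like cells expressing a ratiometric FRET biosensor:
# a flat transmitted-light background with weak membrane rings and internal
# lipid-droplet texture, donor/acceptor fluorescence whose within-cell ratio
# follows a programmed exponential rise after stimulation, Poisson shot
# noise, Gaussian read noise, and 12-bit digitisation. Every cell's mask and
# kinetic parameters are recorded, so segmentation and trace recovery can be
# scored against truth.

#' Generate a ground-truthed synthetic cell population
#'
#' Places `n_cells` non-overlapping, mildly elliptical cells in the field by
#' rejection sampling and draws per-cell photophysics and kinetics. The
#' default geometry is a desk-scale emulation of a wide confocal field:
#' 768 x 768 px at 0.42 um/px (a 2x2-binned crop of a ~570 um field), with
#' cell diameters spanning 15-45 um around a ~30 um mean.
#'
#' The asymptotic relative FRET change `f_final` is drawn either uniformly
#' from `f_final_range` or, when `coupling` is given, as
#' `intercept + slope * diameter + N(0, sigma)` — a linear size-response
#' coupling whose programmed population correlation is
#' `slope * sd(d) / sqrt(slope^2 * var(d) + sigma^2)`. The uptake rate `k_u`
#' is always drawn independently of size.
#'
#' @param n_cells Number of cells (>= 1).
#' @param shape Field extent in pixels, `c(ny, nx)`.
#' @param pixel_size_um Microns per pixel.
#' @param diameter_range_um Uniform range of area-equivalent diameters.
#' @param f_final_range Uniform range of the asymptotic relative FRET change
#'   (ignored when `coupling` is given).
#' @param coupling Optional list `(intercept, slope, sigma)` coupling
#'   `f_final` linearly to diameter (um) with additive Gaussian noise.
#' @param k_u_range Uniform range of uptake rates (1/min).
#' @param baseline_ratio_range Uniform range of unstimulated FRET ratios.
#' @param donor_level_range Uniform range of total sensor fluorescence
#'   (counts) per cell.
#' @param eccentricity Maximum fractional axis asymmetry of the cell
#'   ellipses (area-preserving, so programmed diameters stay exact).
#' @param min_gap_frac Minimum centre distance between two cells as a
#'   fraction of their summed radii beyond 1 (0.05 keeps cells nearly
#'   touching, i.e. a dense field).
#' @param rng_seed Integer seed; the same seed reproduces the population
#'   bit-for-bit.
#' @return A `GroundTruth`: list with `cells` (per-cell parameter
#'   `data.frame`), `masks` (true [cell_mask()]s), `shape`,
#'   `pixel_size_um`, `rng_seed`.
#' @export
generate_population <- function(n_cells = 30, shape = c(768, 768),
                                pixel_size_um = 0.42,
                                diameter_range_um = c(15, 45),
                                f_final_range = c(0.1, 0.4),
                                coupling = NULL,
                                k_u_range = c(0.05, 0.25),
                                baseline_ratio_range = c(0.9, 1.3),
                                donor_level_range = c(900, 1600),
                                eccentricity = 0.08,
                                min_gap_frac = 0.05,
                                rng_seed = 1L) {
  if (n_cells < 1) .stopf("n_cells must be >= 1")
  set.seed(rng_seed)
  ny <- shape[1]; nx <- shape[2]
  d_um <- stats::runif(n_cells, diameter_range_um[1], diameter_range_um[2])
  r_eq <- d_um / 2 / pixel_size_um
  ecc <- stats::runif(n_cells, -eccentricity, eccentricity)
  rx <- r_eq * (1 + ecc)
  ry <- r_eq^2 / rx   # area-preserving, so equivalent diameter stays d_um

  rmax <- pmax(rx, ry)
  if (any(2 * rmax + 6 > min(nx, ny)) ||
      sum(pi * rx * ry) > 0.55 * nx * ny)  # beyond random close packing
    .stopf("cannot fit %d cells in a %d x %d field; use a larger field",
           n_cells, nx, ny)
  cx <- numeric(n_cells); cy <- numeric(n_cells)
  placed <- 0L
  tries <- 0L
  max_tries <- 4000L * n_cells
  while (placed < n_cells) {
    tries <- tries + 1L
    if (tries > max_tries)
      .stopf(paste("could not place %d non-overlapping cells after %d",
                   "attempts; use a larger field or fewer/smaller cells"),
             n_cells, max_tries)
    i <- placed + 1L
    x <- stats::runif(1, rmax[i] + 2, nx - 1 - rmax[i] - 2)
    y <- stats::runif(1, rmax[i] + 2, ny - 1 - rmax[i] - 2)
    if (placed > 0L) {
      j <- seq_len(placed)
      if (any(sqrt((cx[j] - x)^2 + (cy[j] - y)^2) <
              (rmax[j] + rmax[i]) * (1 + min_gap_frac))) next
    }
    cx[i] <- x; cy[i] <- y
    placed <- i
  }

  if (!is.null(coupling)) {
    f_final <- coupling$intercept + coupling$slope * d_um +
      stats::rnorm(n_cells, 0, coupling$sigma)
    f_final <- pmax(f_final, -0.9)
  } else {
    f_final <- stats::runif(n_cells, f_final_range[1], f_final_range[2])
  }
  cells <- data.frame(
    cell_id = seq_len(n_cells), x = cx, y = cy,
    radius_x_px = rx, radius_y_px = ry, diameter_um = d_um,
    f_final = f_final,
    k_u = stats::runif(n_cells, k_u_range[1], k_u_range[2]),
    baseline_ratio = stats::runif(n_cells, baseline_ratio_range[1],
                                  baseline_ratio_range[2]),
    donor_level = stats::runif(n_cells, donor_level_range[1],
                               donor_level_range[2]))
  masks <- lapply(seq_len(n_cells), function(i)
    rasterize_ellipse(list(cell_id = i, x = cx[i], y = cy[i],
                           radius_x = rx[i], radius_y = ry[i]),
                      c(ny, nx)))
  structure(list(cells = cells, masks = masks, shape = c(ny, nx),
                 pixel_size_um = pixel_size_um, rng_seed = rng_seed),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf(
    "GroundTruth: %d cells in %d x %d px (%.3g um/px), mean diameter %.1f um, seed %d\n",
    nrow(x$cells), x$shape[2], x$shape[1], x$pixel_size_um,
    mean(x$cells$diameter_um), x$rng_seed))
  invisible(x)
}

#' Programmed per-cell FRET ratio trajectory
#'
#' `ratio(t) = baseline_ratio * (1 + f_final * (1 - exp(-k_u * t)))`: the
#' ratio each cell's acceptor/donor signal is rendered to follow.
#'
#' @param cell One row of `truth$cells`.
#' @param times_min Times in minutes.
#' @return Numeric ratio vector.
#' @export
programmed_ratio <- function(cell, times_min) {
  cell$baseline_ratio *
    (1 + cell$f_final * (1 - exp(-cell$k_u * times_min)))
}

#' Render a ground-truth population into a time-lapse ImageStack
#'
#' Four channels are drawn. Brightfield: a flat background with a weak dark
#' membrane ring straddling each true boundary and random lipid-droplet
#' blobs inside each cell (the low-contrast texture that makes adipocyte
#' segmentation hard). Donor and acceptor: the cell's total sensor
#' fluorescence is partitioned so that acceptor/donor inside each mask
#' equals the programmed ratio at every timepoint. Direct acceptor: a
#' constant expression-level signal per cell. Poisson shot noise, then
#' Gaussian read noise, then rounding and clipping to the 12-bit range are
#' applied.
#'
#' @param truth A `GroundTruth` from [generate_population()].
#' @param times_min Acquisition times (minutes), starting at 0; default
#'   5-min intervals over 30 min.
#' @param noise List with `shot` (logical, Poisson noise on) and
#'   `read_sigma` (Gaussian read noise SD in counts, >= 0).
#' @param contrast List with `membrane` (fractional brightfield dip of the
#'   membrane ring) and `droplet` (fractional amplitude of droplet texture).
#' @param background List with `brightfield` and `fluorescence` background
#'   levels (counts).
#' @param noise_seed Seed for the noise draws (default derived from the
#'   truth's seed), making rendering deterministic given (truth, seed).
#' @return An [image_stack()].
#' @export
render_timelapse <- function(truth, times_min = seq(0, 30, by = 5),
                             noise = list(shot = TRUE, read_sigma = 4),
                             contrast = list(membrane = 0.10, droplet = 0.05),
                             background = list(brightfield = 2000,
                                               fluorescence = 60),
                             noise_seed = truth$rng_seed + 1L) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (abs(times_min[1]) > 1e-9) .stopf("times must start at 0")
  if (noise$read_sigma < 0) .stopf("read noise sigma must be >= 0")
  set.seed(noise_seed)
  ny <- truth$shape[1]; nx <- truth$shape[2]
  nt <- length(times_min)
  cells <- truth$cells
  n <- nrow(cells)
  maxv <- 4095

  # time-constant brightfield scene
  bf <- matrix(background$brightfield, ny, nx)
  cell_idx <- lapply(truth$masks, function(m) which(m$pixels))
  for (i in seq_len(n)) {
    rm_px <- sqrt(cells$radius_x_px[i] * cells$radius_y_px[i])
    half_w <- 1.2
    pad <- ceiling(pmax(cells$radius_x_px[i], cells$radius_y_px[i]) + 3)
    xs <- max(0, floor(cells$x[i] - pad)):min(nx - 1, ceiling(cells$x[i] + pad))
    ys <- max(0, floor(cells$y[i] - pad)):min(ny - 1, ceiling(cells$y[i] + pad))
    gx <- rep(xs, each = length(ys))
    gy <- rep(ys, times = length(xs))
    s <- sqrt(((gx - cells$x[i]) / cells$radius_x_px[i])^2 +
                ((gy - cells$y[i]) / cells$radius_y_px[i])^2)
    ring <- abs(s - 1) * rm_px <= half_w
    bf[.px_index(gx[ring], gy[ring], ny)] <-
      background$brightfield * (1 - contrast$membrane)
    # lipid droplets: a few random bright/dark blobs well inside the cell
    n_drop <- 2L + stats::rpois(1, length(cell_idx[[i]]) / 1500)
    for (k in seq_len(n_drop)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.55) * rm_px
      dcx <- cells$x[i] + rad * cos(ang)
      dcy <- cells$y[i] + rad * sin(ang)
      dr <- stats::runif(1, 0.08, 0.22) * rm_px
      amp <- sample(c(-1, 1), 1) * contrast$droplet * background$brightfield
      inside <- (gx - dcx)^2 + (gy - dcy)^2 <= dr^2 & s < 1 - half_w / rm_px
      bf[.px_index(gx[inside], gy[inside], ny)] <-
        background$brightfield + amp
    }
  }

  arr <- array(0, dim = c(ny, nx, 4, nt))
  direct_level <- 0.6 * cells$donor_level
  for (t in seq_len(nt)) {
    donor <- matrix(background$fluorescence, ny, nx)
    acceptor <- matrix(background$fluorescence, ny, nx)
    direct <- matrix(background$fluorescence, ny, nx)
    for (i in seq_len(n)) {
      rho <- programmed_ratio(cells[i, ], times_min[t])
      idx <- cell_idx[[i]]
      donor[idx] <- cells$donor_level[i] / (1 + rho)
      acceptor[idx] <- cells$donor_level[i] * rho / (1 + rho)
      direct[idx] <- direct_level[i]
    }
    arr[, , 1, t] <- bf
    arr[, , 2, t] <- donor
    arr[, , 3, t] <- acceptor
    arr[, , 4, t] <- direct
  }
  if (isTRUE(noise$shot)) {
    arr[] <- stats::rpois(length(arr), arr)
  }
  if (noise$read_sigma > 0) {
    arr[] <- arr + stats::rnorm(length(arr), 0, noise$read_sigma)
  }
  arr[] <- pmin(pmax(round(arr), 0), maxv)
  image_stack(arr, pixel_size_um = truth$pixel_size_um,
              time_points_min = times_min, bit_depth = 12L)
}

#' Derive a seed file from ground truth, with realistic user error
#'
#' Emulates a user clicking near — not exactly on — each cell centre and
#' accepting a circular initial guess: seed centres are displaced by up to
#' `offset_frac` of the cell's equivalent radius in a random direction, and
#' seed radii optionally jittered.
#'
#' @param truth A `GroundTruth`.
#' @param offset_frac Maximum centre offset as a fraction of the cell radius.
#' @param radius_jitter_frac Maximum fractional radius error.
#' @param rng_seed Seed for the jitter draws.
#' @return Seed `data.frame` (columns `cell_id`, `x`, `y`, `radius_x`,
#'   `radius_y`) as accepted by [segment_stack()].
#' @export
truth_seeds <- function(truth, offset_frac = 0.2, radius_jitter_frac = 0,
                        rng_seed = truth$rng_seed + 2L) {
  set.seed(rng_seed)
  cells <- truth$cells
  n <- nrow(cells)
  r_eq <- sqrt(cells$radius_x_px * cells$radius_y_px)
  off <- stats::runif(n, 0, offset_frac) * r_eq
  ang <- stats::runif(n, 0, 2 * pi)
  rj <- 1 + stats::runif(n, -radius_jitter_frac, radius_jitter_frac)
  data.frame(cell_id = cells$cell_id,
             x = pmin(pmax(cells$x + off * cos(ang), 0), truth$shape[2] - 1),
             y = pmin(pmax(cells$y + off * sin(ang), 0), truth$shape[1] - 1),
             radius_x = r_eq * rj, radius_y = r_eq * rj)
}

#' Write a ground truth to disk (truth CSV + label TIFF)
#'
#' @param truth A `GroundTruth`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "truth_cells.csv")
  lab <- file.path(dir, "truth_labels.tif")
  utils::write.csv(truth$cells, csv, row.names = FALSE)
  write_mask_labels(truth$masks, lab)
  invisible(c(cells = csv, labels = lab))
}
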