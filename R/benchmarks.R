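# Self-contained validation benchmarks: each one generates ground-truthed
# synthetic fields under the package's default imaging conditions, runs the
# relevant part of the pipeline, and scores the result against truth.

#' Segmentation accuracy benchmark on synthetic low-contrast fields
#'
#' Generates `n_fields` dense fields of round, low-contrast cells (default
#' imaging conditions: weak membrane rings, droplet texture, shot + read
#' noise), seeds each cell with a circular guess whose centre is offset by
#' up to `offset_frac` of its radius, refines with the active contour, and
#' scores every mask against its ground-truth mask with the Jaccard
#' coefficient.
#'
#' @param n_fields Number of independent fields (default 5).
#' @param n_cells Cells per field (default 30).
#' @param n_iterations Active-contour iterations (default 10).
#' @param offset_frac Maximum seed-centre offset as a fraction of the cell
#'   radius (default 0.2).
#' @param rng_seed Base seed; field f uses `rng_seed * 100 + f`.
#' @return List with `mean_jaccard`, `n_cells` scored, and `per_cell`
#'   (`data.frame` of field, cell_id, jaccard, diameter_um).
#' @export
segmentation_benchmark <- function(n_fields = 5, n_cells = 30,
                                   n_iterations = 10, offset_frac = 0.2,
                                   rng_seed = 1L) {
  per_cell <- list()
  for (f in seq_len(n_fields)) {
    fs <- rng_seed * 100L + f
    truth <- generate_population(n_cells = n_cells, rng_seed = fs)
    stack <- render_timelapse(truth, times_min = 0)
    seeds <- truth_seeds(truth, offset_frac = offset_frac)
    seg <- segment_stack(stack, seeds, n_iterations = n_iterations)
    ids <- vapply(seg$masks, function(m) m$cell_id, 1)
    js <- vapply(seq_along(seg$masks), function(i)
      jaccard(seg$masks[[i]], truth$masks[[match(ids[i], truth$cells$cell_id)]]),
      1)
    per_cell[[f]] <- data.frame(field = f, cell_id = ids, jaccard = js,
                                diameter_um = truth$cells$diameter_um[
                                  match(ids, truth$cells$cell_id)])
  }
  per_cell <- do.call(rbind, per_cell)
  list(mean_jaccard = mean(per_cell$jaccard), n_cells = nrow(per_cell),
       per_cell = per_cell)
}

#' Size-response coupling recovery benchmark
#'
#' End-to-end check that the pipeline recovers a programmed diameter
#' dependence of the insulin response. Each replicate simulates a stimulated
#' population of `n_cells` cells (spread over several fields) whose
#' asymptotic relative FRET change is coupled linearly and negatively to
#' diameter (`f_final = intercept + slope * d + N(0, sigma)`), renders
#' low-read-noise time-lapses, segments from offset seeds, quantifies
#' traces, and correlates recovered diameters with recovered total relative
#' FRET changes. The programmed population correlation is
#' `slope * sd(d) / sqrt(slope^2 * var(d) + sigma^2)` (about -0.23 for the
#' defaults).
#'
#' @param n_seeds Number of independent replicates averaged (default 5).
#' @param n_cells Cells per replicate (default 140).
#' @param n_fields Fields each replicate's cells are spread over (default 5).
#' @param coupling List `(intercept, slope, sigma)` of the programmed
#'   size-response coupling.
#' @param times_min Acquisition times (default 5-min intervals over 30 min).
#' @param rng_seed Base seed; replicate s, field f uses
#'   `rng_seed * 1000 + s * 10 + f`.
#' @return List with `mean_r` (mean recovered Pearson r over replicates),
#'   `programmed_r`, `per_seed` r values, and `n_cells` per replicate.
#' @export
size_response_benchmark <- function(n_seeds = 5, n_cells = 140, n_fields = 5,
                                    coupling = list(intercept = 0.35,
                                                    slope = -0.004,
                                                    sigma = 0.1465),
                                    times_min = seq(0, 30, by = 5),
                                    rng_seed = 1L) {
  per_field <- rep(n_cells %/% n_fields, n_fields)
  extra <- n_cells - sum(per_field)
  if (extra > 0) per_field[seq_len(extra)] <- per_field[seq_len(extra)] + 1L
  rs <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    recs <- list()
    for (f in seq_len(n_fields)) {
      fs <- rng_seed * 1000L + s * 10L + f
      truth <- generate_population(n_cells = per_field[f], coupling = coupling,
                                   rng_seed = fs)
      stack <- render_timelapse(truth, times_min = times_min,
                                noise = list(shot = TRUE, read_sigma = 2))
      seeds <- truth_seeds(truth, offset_frac = 0.2)
      seg <- segment_stack(stack, seeds)
      traces <- build_traces(stack, seg)
      recs[[f]] <- data.frame(
        diameter_um = vapply(traces, function(tr) tr$diameter_um, 1),
        total_relative_change = vapply(traces, function(tr)
          total_relative_change(tr$fret_ratio_normalized), 1))
    }
    recs <- do.call(rbind, recs)
    rs[s] <- pearson(recs$diameter_um, recs$total_relative_change)$r
  }
  d_var <- diff(c(15, 45))^2 / 12  # variance of the default diameter draw
  programmed <- coupling$slope * sqrt(d_var) /
    sqrt(coupling$slope^2 * d_var + coupling$sigma^2)
  list(mean_r = mean(rs), programmed_r = programmed, per_seed = rs,
       n_cells = n_cells)
}
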