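# Per-cell intensity extraction and FRET-ratio traces. The raw FRET ratio is
# the sensitized-emission acceptor mean divided by the donor mean inside the
# cell boundary; no bleed-through correction is applied, which is sufficient
# for ratiometric biosensor readouts.

#' Mean pixel intensity inside a cell mask
#'
#' @param stack An [image_stack()].
#' @param mask A [cell_mask()].
#' @param channel Channel name or index.
#' @param t Time index (1-based).
#' @return Arithmetic mean of the intensities under the mask.
#' @export
cell_mean_intensity <- function(stack, mask, channel, t) {
  px <- .mask_pixels(mask)
  if (!any(px)) .stopf("empty mask")
  frame <- get_frame(stack, channel, t)
  if (!identical(dim(px), dim(frame)))
    .stopf("mask extent does not match the stack")
  mean(frame[px])
}

#' Raw FRET ratio
#'
#' Sensitized acceptor emission divided by donor emission. Not the
#' spectrally corrected FRET efficiency, but directly proportional to sensor
#' occupancy and all that biosensor quantification needs.
#'
#' @param acceptor_mean Mean acceptor (donor-excited) intensity.
#' @param donor_mean Mean donor intensity; must be positive.
#' @param cell_id,t Optional context used in error messages.
#' @return `acceptor_mean / donor_mean`.
#' @export
fret_ratio <- function(acceptor_mean, donor_mean, cell_id = NULL, t = NULL) {
  if (any(donor_mean <= 0)) {
    ctx <- if (!is.null(cell_id))
      sprintf(" (cell %s%s)", cell_id,
              if (!is.null(t)) sprintf(", timepoint %s", t) else "") else ""
    .stopf("donor mean must be positive for a FRET ratio%s", ctx)
  }
  acceptor_mean / donor_mean
}

#' Normalize a ratio trace to its first value
#'
#' Element-wise division by the first timepoint, so every cell starts at 1
#' (or 100 in percent mode) and traces from cells with different sensor
#' expression become comparable.
#'
#' @param trace Numeric per-time ratio vector; first value must be positive.
#' @param percent If `TRUE`, scale by 100 for display.
#' @return Normalized trace of the same length.
#' @export
normalize_trace <- function(trace, percent = FALSE) {
  if (length(trace) < 1 || !is.finite(trace[1]) || trace[1] <= 0)
    .stopf("first trace value must be positive to normalize")
  out <- trace / trace[1]
  if (percent) out * 100 else out
}

#' Total relative FRET change of a normalized trace
#'
#' Last value minus first value of the normalized trace: positive when the
#' signal rises over the recording (e.g. insulin-stimulated glucose uptake),
#' negative when it falls. This is the per-cell response magnitude used in
#' the population analyses.
#'
#' @param normalized Normalized per-time vector, length at least 2.
#' @return Signed total relative change.
#' @export
total_relative_change <- function(normalized) {
  if (length(normalized) < 2)
    .stopf("need at least 2 timepoints for a relative change")
  normalized[length(normalized)] - normalized[1]
}

#' Build per-cell traces from a stack and a segmentation
#'
#' For every mask, computes the mean intensity in each channel at each
#' timepoint, the raw FRET ratio (donor-excited acceptor over donor; the
#' direct-acceptor channel is carried along as an expression covariate but
#' not used in the ratio), and the first-value-normalized ratio. Cells whose
#' donor signal is degenerate (mean 0 at any timepoint) are skipped with a
#' warning rather than aborting the field.
#'
#' @param stack An [image_stack()].
#' @param segmentation A [segmentation_result()] or list of [cell_mask()]s.
#' @return List of `CellTrace` objects: fields `cell_id`, `diameter_um`,
#'   `times_min`, `mean_intensity` (channel x time matrix), `fret_ratio`,
#'   `fret_ratio_normalized`.
#' @export
build_traces <- function(stack, segmentation) {
  stopifnot(inherits(stack, "ImageStack"))
  masks <- if (inherits(segmentation, "SegmentationResult"))
    segmentation$masks else segmentation
  nt <- dim(stack$pixels)[4]
  chans <- stack$channel_names
  traces <- list()
  for (m in masks) {
    idx <- which(m$pixels)
    mi <- matrix(0, length(chans), nt,
                 dimnames = list(chans, NULL))
    for (c in seq_along(chans)) for (t in seq_len(nt))
      mi[c, t] <- mean(stack$pixels[, , c, t][idx])
    if (any(mi["donor", ] <= 0)) {
      .warnf("cell %s: donor signal is zero; skipped", m$cell_id)
      next
    }
    ratio <- fret_ratio(mi["acceptor", ], mi["donor", ], cell_id = m$cell_id)
    traces[[length(traces) + 1L]] <- structure(
      list(cell_id = m$cell_id,
           diameter_um = equivalent_diameter(m, stack$pixel_size_um),
           times_min = stack$time_points_min,
           mean_intensity = mi,
           fret_ratio = unname(ratio),
           fret_ratio_normalized = unname(normalize_trace(ratio))),
      class = "CellTrace")
  }
  traces
}

#' @export
print.CellTrace <- function(x, ...) {
  cat(sprintf("CellTrace %s: %.1f um, %d timepoints, ratio %.3f -> %.3f\n",
              x$cell_id, x$diameter_um, length(x$times_min),
              x$fret_ratio[1], x$fret_ratio[length(x$fret_ratio)]))
  invisible(x)
}

#' Flatten traces into a per-(cell, timepoint) data.frame
#'
#' @param traces List of `CellTrace` objects from [build_traces()].
#' @return `data.frame` with one row per cell and timepoint; the schema of
#'   the traces CSV.
#' @export
traces_to_df <- function(traces) {
  if (!length(traces)) .stopf("no traces to tabulate")
  nt <- vapply(traces, function(tr) length(tr$times_min), 1L)
  if (length(unique(nt)) != 1)
    .stopf("traces have mixed timepoint counts")
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = tr$cell_id, time_min = tr$times_min,
               diameter_um = tr$diameter_um,
               mean_brightfield = tr$mean_intensity["brightfield", ],
               mean_donor = tr$mean_intensity["donor", ],
               mean_acceptor = tr$mean_intensity["acceptor", ],
               mean_direct_acceptor = tr$mean_intensity["direct_acceptor", ],
               fret_ratio = tr$fret_ratio,
               fret_ratio_normalized = tr$fret_ratio_normalized)
  }))
}
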