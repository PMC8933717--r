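#' Write per-cell traces to CSV
#'
#' One row per (cell, timepoint) with columns `cell_id`, `time_min`,
#' `diameter_um`, the four channel means, `fret_ratio` and
#' `fret_ratio_normalized`. Values round-trip through [read_traces()] to at
#' least 6 significant digits.
#'
#' @param traces Non-empty list of `CellTrace` objects with equal timepoint
#'   lists (from [build_traces()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- traces_to_df(traces)  # validates non-empty + equal timepoints
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a traces CSV back
#'
#' @param path CSV written by [write_traces()].
#' @return The per-(cell, timepoint) `data.frame`.
#' @export
read_traces <- function(path) utils::read.csv(path)

# ---- boundary overlay -------------------------------------------------------

# 3x5 bitmap glyphs for overlay labels (digits, '.', ':', 'u', 'm', ' ').
# Each glyph is 15 characters, rows top to bottom.
.glyphs <- c(
  "0" = "111101101101111", "1" = "010110010010111",
  "2" = "111001111100111", "3" = "111001111001111",
  "4" = "101101111001001", "5" = "111100111001111",
  "6" = "111100111101111", "7" = "111001001010010",
  "8" = "111101111101111", "9" = "111101111001111",
  "." = "000000000000010", ":" = "000010000010000",
  "u" = "000000101101111", "m" = "000000111111101",
  " " = "000000000000000")

# Stamp `text` into an RGB array (ny x nx x 3) at 0-based (x, y), scale-up
# integer factor `scale`, colour col = c(r, g, b) in [0, 1].
.stamp_text <- function(rgb, text, x, y, col, scale = 2L) {
  chars <- strsplit(text, "")[[1]]
  ny <- dim(rgb)[1]; nx <- dim(rgb)[2]
  cx <- x
  for (ch in chars) {
    bits <- .glyphs[ch]
    if (is.na(bits)) bits <- .glyphs[" "]
    on <- which(matrix(strsplit(bits, "")[[1]] == "1", 5, 3, byrow = TRUE),
                arr.ind = TRUE)
    for (k in seq_len(nrow(on))) {
      py <- y + (on[k, 1] - 1L) * scale
      px <- cx + (on[k, 2] - 1L) * scale
      ys <- py:(py + scale - 1L)
      xs <- px:(px + scale - 1L)
      ys <- ys[ys >= 0 & ys <= ny - 1]
      xs <- xs[xs >= 0 & xs <= nx - 1]
      if (length(ys) && length(xs))
        for (c in 1:3) rgb[ys + 1L, xs + 1L, c] <- col[c]
    }
    cx <- cx + 4L * scale
  }
  rgb
}

#' Write a boundary-overlay PNG
#'
#' Renders the first brightfield frame in greyscale and draws each cell's
#' boundary in a distinct colour, labelled with its `cell_id` and
#' area-equivalent diameter in microns. Boundary colouring is pixel-exact:
#' output pixel (x, y) corresponds to image pixel (x, y).
#'
#' @param stack An [image_stack()].
#' @param masks List of [cell_mask()]s or a `SegmentationResult`; may be
#'   empty, in which case a plain brightfield copy is written.
#' @param path Output PNG path.
#' @param label Draw id/diameter labels (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_overlay <- function(stack, masks, path, label = TRUE) {
  stopifnot(inherits(stack, "ImageStack"))
  if (inherits(masks, "SegmentationResult")) masks <- masks$masks
  bf <- get_frame(stack, "brightfield", 1L)
  ny <- nrow(bf); nx <- ncol(bf)
  rng <- range(bf)
  g <- if (diff(rng) > 0) (bf - rng[1]) / diff(rng) else bf * 0
  rgb <- array(g, dim = c(ny, nx, 3))
  if (length(masks)) {
    cols <- grDevices::col2rgb(grDevices::hcl.colors(max(length(masks), 3),
                                                     "Dark 3")) / 255
    for (i in seq_along(masks)) {
      m <- masks[[i]]
      if (!identical(dim(m$pixels), dim(bf)))
        .stopf("cell %s: mask extent does not match the stack", m$cell_id)
      b <- m$boundary
      ii <- .px_index(b[, "x"], b[, "y"], ny)
      for (c in 1:3) {
        plane <- rgb[, , c]
        plane[ii] <- cols[c, i]
        rgb[, , c] <- plane
      }
      if (label) {
        d <- equivalent_diameter(m, stack$pixel_size_um)
        txt <- sprintf("%s:%.1fum", m$cell_id, d)
        cx <- round(mean(b[, "x"]) - 2 * nchar(txt))
        cy <- round(mean(b[, "y"]) - 5)
        rgb <- .stamp_text(rgb, txt, max(cx, 0), max(cy, 0), cols[, i])
      }
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
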