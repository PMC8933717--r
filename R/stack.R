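#' Canonical channel order for FRET-biosensor stacks
#'
#' Stacks are always held in this order: transmitted-light brightfield, donor
#' (donor excitation / donor emission), acceptor (donor excitation / acceptor
#' emission, i.e. sensitized emission), and direct acceptor (acceptor
#' excitation / acceptor emission, used to confirm sensor expression).
#'
#' @return Character vector of the four canonical channel names.
#' @export
fret_channels <- function() {
  c("brightfield", "donor", "acceptor", "direct_acceptor")
}

#' Construct an ImageStack
#'
#' An `ImageStack` holds a four-channel time-lapse field as a numeric array
#' indexed `[y, x, channel, time]` (row = y, column = x, both 0-based in all
#' user-facing coordinates), together with pixel size and acquisition-time
#' metadata. Intensities are photon counts digitised to `bit_depth` bits and
#' must lie in `[0, 2^bit_depth - 1]`.
#'
#' @param pixels Numeric array with dim `(ny, nx, 4, nt)`.
#' @param pixel_size_um Microns per pixel (> 0).
#' @param time_points_min Strictly increasing acquisition times in minutes,
#'   one per time frame.
#' @param channel_names Channel names in storage order; must be a permutation
#'   of [fret_channels()]. Channels are re-ordered into canonical order.
#' @param bit_depth Integer bit depth of the digitiser (default 12).
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(pixels, pixel_size_um, time_points_min,
                        channel_names = fret_channels(), bit_depth = 12L) {
  if (!is.array(pixels) || length(dim(pixels)) != 4L)
    .stopf("pixels must be a 4-D array indexed (y, x, channel, time)")
  d <- dim(pixels)
  if (d[3] != length(fret_channels()))
    .stopf("expected %d channels, got %d", length(fret_channels()), d[3])
  if (!setequal(channel_names, fret_channels()) ||
      length(channel_names) != length(fret_channels()))
    .stopf("channel_names must be a permutation of: %s",
           paste(fret_channels(), collapse = ", "))
  if (length(time_points_min) != d[4])
    .stopf("time_points_min has %d entries for %d frames",
           length(time_points_min), d[4])
  if (d[4] > 1 && any(diff(time_points_min) <= 0))
    .stopf("time_points_min must be strictly increasing")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    .stopf("pixel_size_um must be > 0")
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1)
    .stopf("intensities must lie in [0, %d] for bit_depth %d",
           2^bit_depth - 1, bit_depth)
  perm <- match(fret_channels(), channel_names)
  pixels <- pixels[, , perm, , drop = FALSE]
  structure(
    list(pixels = pixels, channel_names = fret_channels(),
         pixel_size_um = pixel_size_um,
         time_points_min = as.numeric(time_points_min),
         bit_depth = as.integer(bit_depth)),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "ImageStack: %d x %d px (%.3g um/px), %d channels, %d timepoints (%g-%g min), %d-bit\n",
    d[2], d[1], x$pixel_size_um, d[3], d[4],
    min(x$time_points_min), max(x$time_points_min), x$bit_depth))
  invisible(x)
}

#' Extract one 2-D frame from a stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel name (one of [fret_channels()]) or index.
#' @param t Time index (1-based frame number), default the first frame.
#' @return Numeric matrix `[y, x]`.
#' @export
get_frame <- function(stack, channel, t = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    channel <- match(channel, stack$channel_names)
    if (is.na(channel)) .stopf("unknown channel")
  }
  if (t < 1 || t > dim(stack$pixels)[4]) .stopf("time index out of range")
  stack$pixels[, , channel, t]
}

# ---- TIFF reading -----------------------------------------------------------

.read_pages <- function(path) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) .stopf("cannot parse '%s' as TIFF: %s",
                               path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse accidental RGB pages
    storage.mode(p) <- "double"
    p
  })
}

# Minimal OME-XML reader: axis sizes, dimension order, channel names, pixel
# size. Returns NULL when the description is not OME.
.parse_ome <- function(desc) {
  if (is.null(desc) || !grepl("<OME", desc, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  num_attr <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NA_real_ else as.numeric(v)
  }
  ch <- xml2::xml_attr(xml2::xml_find_all(doc, ".//Channel"), "Name")
  list(size_c = num_attr("SizeC"), size_t = num_attr("SizeT"),
       dimension_order = xml2::xml_attr(px, "DimensionOrder"),
       pixel_size_um = num_attr("PhysicalSizeX"),
       channel_names = if (length(ch) && !anyNA(ch)) ch else NULL)
}

#' Load an xyct image stack from multi-page TIFF file(s)
#'
#' Reads a four-channel time-lapse stack. Either a single multi-page TIFF
#' holds all channels and timepoints (page order set by `layout`), or a
#' character vector gives one file per timepoint, each holding the four
#' channel pages. If the first page carries an OME-XML description, axis
#' sizes, dimension order, channel names and pixel size are taken from it and
#' override `layout`/`channels` where present.
#'
#' @param path Path to a multi-page TIFF, or a vector of paths (one file per
#'   timepoint, in acquisition order).
#' @param channels On-disk channel order; a permutation of [fret_channels()].
#'   Channels are re-ordered into canonical order on load.
#' @param layout Page interleaving for a single file: `"ct"` (channel varies
#'   fastest; the conventional xyct order) or `"tc"` (time varies fastest).
#' @param pixel_size_um Microns per pixel.
#' @param time_points_min Acquisition times in minutes; defaults to 5-min
#'   intervals starting at 0.
#' @param bit_depth Digitiser bit depth (metadata only; data are stored in
#'   16-bit containers on disk).
#' @return An [image_stack()].
#' @export
load_stack <- function(path, channels = fret_channels(),
                       layout = c("ct", "tc"), pixel_size_um = 0.42,
                       time_points_min = NULL, bit_depth = 12L) {
  layout <- match.arg(layout)
  nc <- length(fret_channels())
  if (length(path) > 1L) {
    per_t <- lapply(path, .read_pages)
    n_pages <- vapply(per_t, length, 1L)
    if (any(n_pages != nc))
      .stopf("each per-timepoint file must hold %d channel pages; got %s",
             nc, paste(n_pages, collapse = ", "))
    pages <- unlist(per_t, recursive = FALSE)
    nt <- length(path)
    layout <- "ct"
  } else {
    pages <- .read_pages(path)
    ome <- .parse_ome(attr(pages[[1]], "description"))
    if (!is.null(ome)) {
      if (!is.na(ome$size_c) && ome$size_c != nc)
        .stopf("OME metadata declares %d channels; %d required", ome$size_c, nc)
      if (!is.na(ome$size_t)) {
        if (length(pages) != nc * ome$size_t)
          .stopf("OME metadata declares %d pages but file has %d",
                 nc * ome$size_t, length(pages))
      }
      if (!is.null(ome$dimension_order))
        layout <- if (regexpr("C", ome$dimension_order) <
                      regexpr("T", ome$dimension_order)) "ct" else "tc"
      if (!is.null(ome$channel_names) &&
          setequal(ome$channel_names, fret_channels()))
        channels <- ome$channel_names
      if (!is.na(ome$pixel_size_um) && ome$pixel_size_um > 0)
        pixel_size_um <- ome$pixel_size_um
    }
    if (length(pages) %% nc != 0L)
      .stopf("file has %d pages, not a multiple of %d channels",
             length(pages), nc)
    nt <- length(pages) %/% nc
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    .stopf("inconsistent frame shapes across pages")
  ny <- dims[1, 1]; nx <- dims[2, 1]
  arr <- array(0, dim = c(ny, nx, nc, nt))
  for (t in seq_len(nt)) for (c in seq_len(nc)) {
    p <- if (layout == "ct") (t - 1L) * nc + c else (c - 1L) * nt + t
    arr[, , c, t] <- pages[[p]]
  }
  if (is.null(time_points_min)) time_points_min <- (seq_len(nt) - 1) * 5
  image_stack(arr, pixel_size_um = pixel_size_um,
              time_points_min = time_points_min,
              channel_names = channels, bit_depth = bit_depth)
}

#' Write an ImageStack to a multi-page TIFF
#'
#' Pages are written in canonical channel-fastest (xyct) order into 16-bit
#' containers, so 12-bit data round-trip bit-exactly through [load_stack()].
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$pixels)
  pages <- vector("list", d[3] * d[4])
  i <- 0L
  for (t in seq_len(d[4])) for (c in seq_len(d[3])) {
    i <- i + 1L
    pages[[i]] <- round(stack$pixels[, , c, t]) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
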