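#' Construct a CellMask
#'
#' A `CellMask` is the pixel set of one segmented cell: a logical matrix with
#' the same spatial extent as the image, a `cell_id` label, and an ordered
#' boundary contour. The pixels must form exactly one 8-connected component;
#' boundary pixels are members of the mask adjacent to at least one
#' non-member.
#'
#' @param cell_id Cell label.
#' @param pixels Logical matrix `[y, x]`, at least one `TRUE` pixel.
#' @param check If `TRUE` (default) verify single-component connectivity.
#' @return An object of class `CellMask` with fields `cell_id`, `pixels`,
#'   `boundary` (integer matrix, columns `x`, `y`, 0-based, ordered along the
#'   contour).
#' @export
cell_mask <- function(cell_id, pixels, check = TRUE) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    .stopf("pixels must be a logical matrix")
  if (!any(pixels)) .stopf("cell %s: mask is empty", cell_id)
  if (check && .n_components8(pixels) != 1L)
    .stopf("cell %s: mask is not a single 8-connected component", cell_id)
  oc <- EBImage::ocontour(pixels * 1L)[[1]]
  boundary <- cbind(x = oc[, 2], y = oc[, 1])
  structure(list(cell_id = cell_id, pixels = pixels, boundary = boundary),
            class = "CellMask")
}

#' @export
print.CellMask <- function(x, ...) {
  cat(sprintf("CellMask %s: %d px in a %d x %d field\n", x$cell_id,
              sum(x$pixels), ncol(x$pixels), nrow(x$pixels)))
  invisible(x)
}

.mask_pixels <- function(m) {
  if (inherits(m, "CellMask")) m$pixels else m
}

.mask_shape <- function(shape) {
  if (inherits(shape, "ImageStack")) dim(shape$pixels)[1:2]
  else if (is.matrix(shape)) dim(shape)
  else as.integer(shape)  # c(ny, nx)
}

#' Rasterize a seed ellipse into a pixel mask
#'
#' The mask contains exactly the pixels `(x, y)` (0-based integer centres)
#' satisfying `((x - cx)/rx)^2 + ((y - cy)/ry)^2 <= 1`. An ellipse extending
#' beyond the image is clipped and flagged with a warning and a `clipped`
#' attribute rather than silently cropped.
#'
#' @param seed One-row seed `data.frame` (columns `cell_id`, `x`, `y`,
#'   `radius_x`, `radius_y`) or a list with those fields.
#' @param shape Image extent: `c(ny, nx)`, a matrix, or an [image_stack()].
#' @return A [cell_mask()]; attribute `clipped` is `TRUE` when the ellipse
#'   ran off the image edge.
#' @export
rasterize_ellipse <- function(seed, shape) {
  sh <- .mask_shape(shape)
  ny <- sh[1]; nx <- sh[2]
  cx <- seed$x; cy <- seed$y
  rx <- seed$radius_x; ry <- seed$radius_y
  if (rx <= 0 || ry <= 0) .stopf("seed radii must be positive")
  if (cx < 0 || cx > nx - 1 || cy < 0 || cy > ny - 1)
    .stopf("cell %s: seed centre (%g, %g) outside image", seed$cell_id, cx, cy)
  clipped <- (cx - rx < 0 || cx + rx > nx - 1 || cy - ry < 0 || cy + ry > ny - 1)
  xs <- max(0, floor(cx - rx)):min(nx - 1, ceiling(cx + rx))
  ys <- max(0, floor(cy - ry)):min(ny - 1, ceiling(cy + ry))
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  inside <- ((gx - cx) / rx)^2 + ((gy - cy) / ry)^2 <= 1
  m <- matrix(FALSE, ny, nx)
  m[.px_index(gx[inside], gy[inside], ny)] <- TRUE
  if (!any(m))  # sub-pixel ellipse away from any pixel centre: keep the centre
    m[.px_index(round(cx), round(cy), ny)] <- TRUE
  if (clipped)
    .warnf("cell %s: seed ellipse clipped at the image boundary", seed$cell_id)
  out <- cell_mask(seed$cell_id, m, check = FALSE)
  attr(out, "clipped") <- clipped
  out
}

#' Area-equivalent cell diameter
#'
#' Diameter of the circle with the same area as the mask:
#' `2 * sqrt(area_px / pi) * pixel_size_um`. This is the standard size measure
#' for near-round cells and reduces to the true diameter on discs.
#'
#' @param mask A [cell_mask()] or logical matrix.
#' @param pixel_size_um Microns per pixel.
#' @return Diameter in microns.
#' @export
equivalent_diameter <- function(mask, pixel_size_um) {
  px <- .mask_pixels(mask)
  area <- sum(px)
  if (area == 0) .stopf("empty mask has no diameter")
  2 * sqrt(area / pi) * pixel_size_um
}

#' Jaccard similarity (intersection over union) of two masks
#'
#' `|A intersect B| / |A union B|`, ranging from 0 (disjoint) to 1 (perfect
#' match); the standard agreement score between a computed segmentation and a
#' reference mask.
#'
#' @param mask_a,mask_b [cell_mask()] objects or logical matrices sharing one
#'   spatial extent.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard <- function(mask_a, mask_b) {
  a <- .mask_pixels(mask_a)
  b <- .mask_pixels(mask_b)
  if (!identical(dim(a), dim(b)))
    .stopf("masks have different spatial extents")
  uni <- sum(a | b)
  if (uni == 0) .stopf("Jaccard undefined: both masks are empty")
  sum(a & b) / uni
}

#' Construct a SegmentationResult
#'
#' Bundles the masks of one segmented field with the method and parameters
#' used, for provenance. Masks must carry unique `cell_id`s and be pairwise
#' disjoint.
#'
#' @param masks List of [cell_mask()] objects.
#' @param method `"active_contour"` or `"threshold_watershed"`.
#' @param parameters Named list of the settings used (e.g. `n_iterations`,
#'   `threshold`).
#' @return An object of class `SegmentationResult`.
#' @export
segmentation_result <- function(masks,
                                method = c("active_contour",
                                           "threshold_watershed"),
                                parameters = list()) {
  method <- match.arg(method)
  ids <- vapply(masks, function(m) as.character(m$cell_id), "")
  if (anyDuplicated(ids)) .stopf("duplicate cell_id among masks")
  if (length(masks) > 1) {
    acc <- Reduce(`+`, lapply(masks, function(m) m$pixels * 1L))
    if (max(acc) > 1L) .stopf("masks are not pairwise disjoint")
  }
  structure(list(masks = masks, method = method, parameters = parameters),
            class = "SegmentationResult")
}

#' @export
print.SegmentationResult <- function(x, ...) {
  cat(sprintf("SegmentationResult: %d cells by %s (%s)\n", length(x$masks),
              x$method,
              paste(names(x$parameters), unlist(x$parameters), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Write masks as a 16-bit label image TIFF
#'
#' Background pixels are 0; each cell's pixels carry its integer `cell_id`.
#'
#' @param masks List of [cell_mask()] objects or a `SegmentationResult`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_labels <- function(masks, path) {
  if (inherits(masks, "SegmentationResult")) masks <- masks$masks
  d <- dim(masks[[1]]$pixels)
  lab <- matrix(0L, d[1], d[2])
  for (m in masks) lab[m$pixels] <- as.integer(m$cell_id)
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label image back into masks
#'
#' @param path Label TIFF written by [write_mask_labels()].
#' @return List of [cell_mask()] objects, one per non-zero label.
#' @export
read_mask_labels <- function(path) {
  lab <- tiff::readTIFF(path, as.is = TRUE)
  ids <- sort(unique(lab[lab > 0]))
  lapply(ids, function(i) cell_mask(i, lab == i, check = FALSE))
}
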