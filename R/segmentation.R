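# Seeded segmentation of round cells. Two paths, matching how biosensor
# fields are segmented in practice: (1) an initial per-cell ellipse refined by
# an active contour on the brightfield image; (2) an intensity threshold on a
# fluorescence image followed by click-seeded watershed splitting of touching
# cells.

#' Smoothed gradient-magnitude edge map of a frame
#'
#' Gradient magnitude of the Gaussian-smoothed image, blurred once more to
#' widen each edge's basin of attraction — the energy landscape the active
#' contour descends. Cell membranes appear as broad ridges.
#'
#' @param image 2-D numeric matrix.
#' @param sigma Pre-gradient Gaussian smoothing (pixels).
#' @param attract_sigma Post-gradient smoothing (pixels).
#' @return Numeric matrix of edge responses, same extent as `image`.
#' @export
edge_map <- function(image, sigma = 2, attract_sigma = 3) {
  edge <- .gradient_magnitude(image, sigma)
  if (attract_sigma > 0) edge <- as.matrix(EBImage::gblur(edge, attract_sigma))
  edge
}

# Radial profile of a mask around a centre: for each of n_points angles, the
# distance from (cx, cy) to the last mask pixel along the ray (star-convex
# reading of the mask).
.polar_radii <- function(pixels, cx, cy, n_points) {
  ny <- nrow(pixels); nx <- ncol(pixels)
  theta <- 2 * pi * (seq_len(n_points) - 1) / n_points
  rmax <- sqrt(nx^2 + ny^2)
  steps <- seq(0, rmax, by = 0.5)
  ct <- cos(theta); st <- sin(theta)
  r <- numeric(n_points)
  inside_prev <- rep(TRUE, n_points)
  for (s in steps[-1]) {
    xx <- pmin(pmax(round(cx + s * ct), 0), nx - 1)
    yy <- pmin(pmax(round(cy + s * st), 0), ny - 1)
    inside <- pixels[.px_index(xx, yy, ny)] & inside_prev
    r[inside] <- s
    inside_prev <- inside
    if (!any(inside)) break
  }
  pmax(r, 1)
}

# Fill the star-convex polygon r(theta) about (cx, cy) into a logical matrix.
.fill_polar <- function(r, cx, cy, shape) {
  ny <- shape[1]; nx <- shape[2]
  n <- length(r)
  rmax <- max(r)
  xs <- max(0, floor(cx - rmax)):min(nx - 1, ceiling(cx + rmax))
  ys <- max(0, floor(cy - rmax)):min(ny - 1, ceiling(cy + rmax))
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  dx <- gx - cx; dy <- gy - cy
  rad <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx) %% (2 * pi)
  pos <- ang / (2 * pi) * n          # fractional index into r, periodic
  i0 <- floor(pos) %% n
  frac <- pos - floor(pos)
  r_here <- r[i0 + 1] * (1 - frac) + r[(i0 + 1L) %% n + 1] * frac
  m <- matrix(FALSE, ny, nx)
  keep <- rad <= r_here
  m[.px_index(gx[keep], gy[keep], ny)] <- TRUE
  m
}

#' Refine a seed mask by active contouring on the brightfield image
#'
#' A greedy polar snake: the initial mask is read as a star-convex radial
#' profile around its centroid, and radial control points are moved to
#' minimise an energy combining attraction to the Gaussian-smoothed
#' brightfield gradient magnitude (the cell membrane shows as a gradient
#' ridge) with a curvature penalty keeping the contour smooth. Each iteration
#' a control point may move at most `search_px` pixels radially, so
#' `n_iterations` hard-caps how far the input ellipse can deform;
#' `n_iterations = 0` returns the initial mask unchanged.
#'
#' @param image 2-D numeric matrix: the brightfield frame at the segmentation
#'   timepoint.
#' @param init Initial [cell_mask()] (typically a rasterized seed ellipse).
#' @param n_iterations Iteration cap (default 10, the setting that routinely
#'   locates adipocyte boundaries).
#' @param sigma Gaussian smoothing (pixels) applied before taking gradients.
#' @param attract_sigma Extra smoothing of the gradient-magnitude map that
#'   widens each edge's basin of attraction.
#' @param n_points Number of radial control points on the contour.
#' @param search_px Radial search window per iteration (pixels).
#' @param alpha Curvature penalty weight (energy per squared pixel of
#'   deviation from the neighbour mean radius).
#' @param balloon Outward (> 0) or inward (< 0) pressure per iteration in
#'   pixels of preferred radial drift; 0 (default) deforms only toward
#'   contours.
#' @param edge_map Optional precomputed smoothed gradient-magnitude map (see
#'   [edge_map()]); computed from `image` when `NULL`. Lets one map be
#'   shared across the cells of a field.
#' @return A refined [cell_mask()] with the same `cell_id`.
#' @export
active_contour_refine <- function(image, init, n_iterations = 10, sigma = 2,
                                  attract_sigma = 3, n_points = 72,
                                  search_px = 3, alpha = 0.02, balloon = 0,
                                  edge_map = NULL) {
  stopifnot(is.matrix(image))
  if (!inherits(init, "CellMask")) .stopf("init must be a CellMask")
  if (!any(init$pixels)) .stopf("cell %s: empty init mask", init$cell_id)
  if (n_iterations < 0) .stopf("n_iterations must be non-negative")
  if (n_iterations == 0) return(init)
  ny <- nrow(image); nx <- ncol(image)
  if (!identical(dim(init$pixels), dim(image)))
    .stopf("init mask extent does not match the image")

  idx <- which(init$pixels)
  cy <- mean((idx - 1L) %% ny)
  cx <- mean((idx - 1L) %/% ny)
  r <- .polar_radii(init$pixels, cx, cy, n_points)

  edge <- if (is.null(edge_map)) edge_map(image, sigma, attract_sigma)
          else edge_map
  # normalise edge response locally, over the annulus the snake can reach
  reach <- max(r) + search_px * n_iterations
  ys <- max(1, floor(cy + 1 - reach)):min(ny, ceiling(cy + 1 + reach))
  xs <- max(1, floor(cx + 1 - reach)):min(nx, ceiling(cx + 1 + reach))
  scale <- stats::quantile(edge[ys, xs], 0.995)
  if (scale <= 0) scale <- 1

  theta <- 2 * pi * (seq_len(n_points) - 1) / n_points
  ct <- cos(theta); st <- sin(theta)
  drs <- -search_px:search_px
  left <- c(n_points, seq_len(n_points - 1))
  right <- c(2:n_points, 1)
  for (it in seq_len(n_iterations)) {
    rbar <- (r[left] + r[right]) / 2
    best_e <- rep(Inf, n_points)
    best_r <- r
    for (dr in drs) {
      rc <- pmin(pmax(r + dr, 1), max(nx, ny))
      e_edge <- pmin(.interp_bilinear(edge, cx + rc * ct, cy + rc * st) /
                       scale, 1.5)
      e <- -e_edge + alpha * (rc - rbar)^2 + 0.003 * abs(dr) - balloon * dr
      take <- e < best_e
      best_e[take] <- e[take]
      best_r[take] <- rc[take]
    }
    if (all(best_r == r)) break
    r <- best_r
  }
  m <- .fill_polar(r, cx, cy, c(ny, nx))
  if (!any(m))
    .stopf("cell %s: contour collapsed to zero pixels", init$cell_id)
  m <- .largest_component8(m)
  cell_mask(init$cell_id, m, check = FALSE)
}

#' Threshold a fluorescence frame into foreground regions
#'
#' Pixels at or above the threshold are foreground; holes are filled and
#' components smaller than `min_area` pixels are removed, mirroring the
#' interactive threshold-slider workflow for spread, fluorescent cells.
#'
#' @param image 2-D numeric matrix (a fluorescence frame).
#' @param threshold Intensity cutoff (inclusive).
#' @param min_area Minimum surviving component area in pixels (default 50).
#' @param fill_holes Fill enclosed background holes (default `TRUE`).
#' @return Logical foreground matrix. An empty mask is valid and raises a
#'   warning.
#' @export
threshold_regions <- function(image, threshold, min_area = 50,
                              fill_holes = TRUE) {
  stopifnot(is.matrix(image), is.finite(threshold))
  bw <- image >= threshold
  if (!any(bw)) {
    .warnf("threshold %g is above the image maximum: empty mask", threshold)
    return(bw)
  }
  if (fill_holes) bw <- as.matrix(EBImage::fillHull(bw * 1L)) > 0
  if (min_area > 1) {
    lab <- EBImage::bwlabel(bw * 1L)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    bw <- matrix(lab %in% keep, nrow(bw), ncol(bw))
    if (!any(bw))
      .warnf("no component reaches min_area = %d: empty mask", min_area)
  }
  bw
}

#' Split a thresholded region into cells by click-seeded watershedding
#'
#' Each clicked point is the centre of one cell. Within each connected
#' component of the region that contains at least one click, every pixel is
#' assigned to the click it is nearest to (the distance-transform basins);
#' the ridge pixels equidistant between clicks go to the lower `cell_id`.
#' Components without clicks are left unassigned.
#'
#' @param region Logical foreground matrix (from [threshold_regions()]).
#' @param clicks `data.frame` with columns `cell_id`, `x`, `y` (0-based
#'   pixel coordinates inside the region).
#' @return List of pairwise-disjoint [cell_mask()] objects whose union is
#'   exactly the clicked components.
#' @export
watershed_split <- function(region, clicks) {
  stopifnot(is.matrix(region), is.logical(region))
  if (nrow(clicks) < 1) .stopf("at least one click is required")
  ny <- nrow(region); nx <- ncol(region)
  clicks <- clicks[order(clicks$cell_id), , drop = FALSE]
  ci <- .px_index(clicks$x, clicks$y, ny)
  out_of <- !region[ci]
  if (any(out_of))
    .stopf("click(s) outside the thresholded region: %s",
           paste(sprintf("(%g, %g)", clicks$x[out_of], clicks$y[out_of]),
                 collapse = ", "))

  # group clicks by the 8-connected component each belongs to
  comp_of <- integer(nrow(clicks))
  comp_px <- list()
  for (i in seq_len(nrow(clicks))) {
    if (comp_of[i] != 0L) next
    px <- .flood8(region, ci[i])
    comp_px[[length(comp_px) + 1L]] <- px
    members <- ci %in% px
    comp_of[members] <- length(comp_px)
  }

  assign_lab <- matrix(0L, ny, nx)
  for (k in seq_along(comp_px)) {
    px <- comp_px[[k]]
    in_comp <- which(comp_of == k)
    xx <- (px - 1L) %/% ny
    yy <- (px - 1L) %% ny
    best_d <- rep(Inf, length(px))
    best_i <- rep(0L, length(px))
    for (i in in_comp) {  # ascending cell_id: ridge ties go to the lower id
      d <- (xx - clicks$x[i])^2 + (yy - clicks$y[i])^2
      take <- d < best_d
      best_d[take] <- d[take]
      best_i[take] <- i
    }
    assign_lab[px] <- best_i
  }

  empty <- setdiff(seq_len(nrow(clicks)), unique(assign_lab[assign_lab > 0]))
  if (length(empty))
    .warnf("click(s) %s collapsed into another basin (tie broken by label order)",
           paste(clicks$cell_id[empty], collapse = ", "))

  # each cell keeps the component of its basin containing its click; orphan
  # fragments are re-attached to the nearest adjacent cell so the union still
  # covers the clicked region exactly
  settled <- matrix(FALSE, ny, nx)
  for (i in setdiff(seq_len(nrow(clicks)), empty)) {
    basin <- assign_lab == i
    keep <- .flood8(basin, ci[i])
    drop <- which(basin)[!(which(basin) %in% keep)]
    assign_lab[drop] <- 0L
    settled[keep] <- TRUE
  }
  clicked <- matrix(FALSE, ny, nx)
  for (px in comp_px) clicked[px] <- TRUE
  repeat {
    orphan <- which(clicked & !settled)
    if (!length(orphan)) break
    moved <- FALSE
    offs <- c(-1L, 1L, -ny, ny, -ny - 1L, -ny + 1L, ny - 1L, ny + 1L)
    for (p in orphan) {
      nb <- p + offs
      nb <- nb[nb >= 1 & nb <= ny * nx]
      labs <- unique(assign_lab[nb][settled[nb]])
      labs <- labs[labs > 0]
      if (!length(labs)) next
      xx <- (p - 1L) %/% ny; yy <- (p - 1L) %% ny
      d <- (clicks$x[labs] - xx)^2 + (clicks$y[labs] - yy)^2
      assign_lab[p] <- labs[which.min(d)]
      settled[p] <- TRUE
      moved <- TRUE
    }
    if (!moved) break
  }

  lapply(setdiff(seq_len(nrow(clicks)), empty), function(i)
    cell_mask(clicks$cell_id[i], assign_lab == i, check = FALSE))
}

#' Segment a full field from seeds
#'
#' Runs one of the two segmentation paths on the first timepoint and returns
#' disjoint per-cell masks that are reused for all timepoints (cells are
#' assumed stationary over the recording).
#'
#' For `method = "active_contour"`, each seed ellipse is rasterized and
#' refined on the brightfield frame; pixels claimed by several contours are
#' resolved to the cell with the nearest seed centre. For
#' `method = "threshold_watershed"`, the chosen fluorescence channel is
#' thresholded and split at the click points.
#'
#' @param stack An [image_stack()].
#' @param seeds Seed ellipses ([load_seeds()]) for the active-contour path,
#'   or click points ([load_clicks()]) for the watershed path.
#' @param method `"active_contour"` (default) or `"threshold_watershed"`.
#' @param n_iterations Active-contour iteration cap (default 10).
#' @param threshold Intensity threshold (watershed path).
#' @param channel Channel thresholded on the watershed path (default
#'   `"donor"`).
#' @param min_area Minimum component area for thresholding.
#' @param ... Further arguments passed to [active_contour_refine()].
#' @return A [segmentation_result()].
#' @export
segment_stack <- function(stack, seeds,
                          method = c("active_contour", "threshold_watershed"),
                          n_iterations = 10, threshold = NULL,
                          channel = "donor", min_area = 50, ...) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "ImageStack"))
  if (method == "threshold_watershed") {
    if (is.null(threshold)) .stopf("threshold is required for watershedding")
    frame <- get_frame(stack, channel, 1L)
    region <- threshold_regions(frame, threshold, min_area = min_area)
    masks <- watershed_split(region, seeds)
    return(segmentation_result(masks, "threshold_watershed",
                               list(threshold = threshold, channel = channel,
                                    min_area = min_area)))
  }
  bf <- get_frame(stack, "brightfield", 1L)
  em <- edge_map(bf)
  masks <- lapply(seq_len(nrow(seeds)), function(i) {
    init <- rasterize_ellipse(seeds[i, ], dim(bf))
    active_contour_refine(bf, init, n_iterations = n_iterations,
                          edge_map = em, ...)
  })
  masks <- .resolve_overlaps(masks, seeds)
  segmentation_result(masks, "active_contour",
                      list(n_iterations = n_iterations))
}

# Contested pixels go to the cell with the nearest seed centre (lower id on
# ties); each mask then keeps the component containing its seed centre.
.resolve_overlaps <- function(masks, seeds) {
  if (length(masks) < 2) return(masks)
  ny <- nrow(masks[[1]]$pixels)
  claims <- tabulate(unlist(lapply(masks, function(m) which(m$pixels))),
                     nbins = length(masks[[1]]$pixels))
  contested <- which(claims > 1L)
  if (length(contested)) {
    xx <- (contested - 1L) %/% ny
    yy <- (contested - 1L) %% ny
    best_d <- rep(Inf, length(contested))
    best_i <- rep(0L, length(contested))
    for (i in seq_along(masks)) {
      mine <- masks[[i]]$pixels[contested]
      d <- (xx - seeds$x[i])^2 + (yy - seeds$y[i])^2
      take <- mine & d < best_d
      best_d[take] <- d[take]
      best_i[take] <- i
    }
    for (i in seq_along(masks)) {
      lose <- contested[best_i != i]
      px <- masks[[i]]$pixels
      px[lose] <- FALSE
      if (!any(px))
        .stopf("cell %s: mask vanished while resolving overlaps",
               masks[[i]]$cell_id)
      centre <- .px_index(round(seeds$x[i]), round(seeds$y[i]), ny)
      if (!px[centre]) px <- .largest_component8(px)
      else {
        keep <- .flood8(px, centre)
        px[] <- FALSE
        px[keep] <- TRUE
      }
      masks[[i]] <- cell_mask(masks[[i]]$cell_id, px, check = FALSE)
    }
  }
  masks
}
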