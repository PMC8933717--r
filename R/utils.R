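# Internal helpers shared across modules. Pixel coordinates are 0-based
# (x, y) = (column, row) with origin top-left in all user-facing structures;
# internally R matrices are indexed [row = y + 1, col = x + 1].

#' @keywords internal
.px_index <- function(x, y, ny) {
  # linear index into an ny-row matrix for 0-based (x, y)
  (x) * ny + y + 1L
}

# 8-connected flood fill from one or more start indices within a logical
# matrix. Vectorised frontier BFS: each sweep expands the whole frontier by
# the 8 neighbour offsets, so cost scales with region diameter, not area.
#' @keywords internal
.flood8 <- function(mask, start_idx) {
  ny <- nrow(mask)
  nx <- ncol(mask)
  n <- ny * nx
  offs <- c(-1L, 1L, -ny, ny, -ny - 1L, -ny + 1L, ny - 1L, ny + 1L)
  visited <- logical(n)
  start_idx <- start_idx[mask[start_idx]]
  visited[start_idx] <- TRUE
  frontier <- start_idx
  while (length(frontier) > 0L) {
    row0 <- (frontier - 1L) %% ny  # 0-based row of each frontier pixel
    nb <- rep(frontier, times = 8L) + rep(offs, each = length(frontier))
    # drop wrap-around across matrix columns: neighbour row must differ by <= 1
    nb_row <- (nb - 1L) %% ny
    ok <- nb >= 1L & nb <= n & abs(nb_row - rep(row0, times = 8L)) <= 1L
    nb <- nb[ok]
    nb <- nb[mask[nb] & !visited[nb]]
    nb <- unique(nb)
    visited[nb] <- TRUE
    frontier <- nb
  }
  which(visited)
}

# Label all 8-connected components; returns integer matrix (0 = background).
#' @keywords internal
.label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  todo <- which(mask)
  k <- 0L
  while (length(todo) > 0L) {
    k <- k + 1L
    comp <- .flood8(mask, todo[1L])
    lab[comp] <- k
    mask[comp] <- FALSE
    todo <- which(mask)
  }
  lab
}

#' @keywords internal
.largest_component8 <- function(mask) {
  lab <- .label8(mask)
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' @keywords internal
.n_components8 <- function(mask) max(.label8(mask))

# Gradient magnitude of a Gaussian-smoothed image (central differences).
#' @keywords internal
.gradient_magnitude <- function(img, sigma = 2) {
  if (sigma > 0) img <- EBImage::gblur(img, sigma = sigma)
  img <- as.matrix(img)
  ny <- nrow(img)
  nx <- ncol(img)
  gy <- matrix(0, ny, nx)
  gx <- matrix(0, ny, nx)
  gy[2:(ny - 1), ] <- (img[3:ny, ] - img[1:(ny - 2), ]) / 2
  gx[, 2:(nx - 1)] <- (img[, 3:nx] - img[, 1:(nx - 2)]) / 2
  sqrt(gx^2 + gy^2)
}

# Bilinear interpolation of matrix values at continuous 0-based (x, y).
# Points outside the image clamp to the border.
#' @keywords internal
.interp_bilinear <- function(m, x, y) {
  ny <- nrow(m)
  nx <- ncol(m)
  x <- pmin(pmax(x, 0), nx - 1)
  y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2)
  y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0
  fy <- y - y0
  i00 <- .px_index(x0, y0, ny)
  m[i00] * (1 - fx) * (1 - fy) + m[i00 + ny] * fx * (1 - fy) +
    m[i00 + 1L] * (1 - fx) * fy + m[i00 + ny + 1L] * fx * fy
}

#' @keywords internal
.stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
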