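# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Jaccard by explicit set operations on coordinate lists
oracle_jaccard <- function(a, b) {
  ia <- which(a); ib <- which(b)
  length(intersect(ia, ib)) / length(union(ia, ib))
}

# mean intensity by an explicit double loop
oracle_mean_intensity <- function(frame, mask) {
  s <- 0; n <- 0L
  for (i in seq_len(nrow(frame))) for (j in seq_len(ncol(frame))) {
    if (mask[i, j]) { s <- s + frame[i, j]; n <- n + 1L }
  }
  s / n
}

# pooled-variance two-sample t statistic and p, from the textbook formula
oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tstat,
       p_value = 2 * pt(-abs(tstat), df = na + nb - 2))
}

# KS D by brute-force supremum of |ECDF_a - ECDF_b| over all breakpoints
oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(p) mean(a <= p) - mean(b <= p), 1)))
}

# Pearson r from the definitional sums
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# R^2 straight from the formula
oracle_r2 <- function(obs, fit) 1 - sum((obs - fit)^2) /
  sum((obs - mean(obs))^2)

# 4-connected component labelling by queue flood fill (independent of the
# package's labelling and of EBImage)
oracle_label4 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  k <- 0L
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% ny + 1L; c <- (p - 1L) %/% ny + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] < 1 || d[1] > ny || d[2] < 1 || d[2] > nx) next
        q <- (d[2] - 1L) * ny + d[1]
        if (mask[q] && lab[q] == 0L) { lab[q] <- k; queue <- c(queue, q) }
      }
    }
  }
  lab
}

# pixels >= threshold surviving a 4-connected minimum-area filter
oracle_threshold_count <- function(image, threshold, min_area) {
  lab <- oracle_label4(image >= threshold)
  if (max(lab) == 0) return(0L)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes[sizes >= min_area])
}

# a small noiseless stack with hand-set channel frames
flat_stack <- function(ny = 16, nx = 16, nt = 1, brightfield = 100,
                       donor = 100, acceptor = 100, direct = 100,
                       pixel_size_um = 1) {
  arr <- array(0, dim = c(ny, nx, 4, nt))
  arr[, , 1, ] <- brightfield
  arr[, , 2, ] <- donor
  arr[, , 3, ] <- acceptor
  arr[, , 4, ] <- direct
  image_stack(arr, pixel_size_um = pixel_size_um,
              time_points_min = (seq_len(nt) - 1) * 5)
}

disc_mask <- function(ny, nx, cx, cy, r) {
  gx <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  gy <- matrix(rep(0:(ny - 1), times = nx), ny, nx)
  (gx - cx)^2 + (gy - cy)^2 <= r^2
}
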