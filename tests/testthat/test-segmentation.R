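test_that("ellipse rasterization matches the pixel-inclusion inequality", {
  shape <- c(24, 24)
  # unit circle at (10, 10): the 5-pixel plus shape
  m <- rasterize_ellipse(list(cell_id = 1, x = 10, y = 10,
                              radius_x = 1, radius_y = 1), shape)
  got <- which(m$pixels, arr.ind = TRUE)
  want <- rbind(c(11, 11), c(10, 11), c(12, 11), c(11, 10), c(11, 12))
  expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))

  # sub-unit radius keeps only the centre pixel
  m <- rasterize_ellipse(list(cell_id = 1, x = 10, y = 10,
                              radius_x = 0.4, radius_y = 0.4), shape)
  expect_equal(sum(m$pixels), 1)
  expect_true(m$pixels[11, 11])

  # large ellipse: area within 5% of pi * rx * ry, and exactly the
  # brute-force enumeration of the inequality
  shape <- c(80, 100)
  m <- rasterize_ellipse(list(cell_id = 1, x = 49, y = 39,
                              radius_x = 30, radius_y = 10), shape)
  expect_equal(sum(m$pixels) / (pi * 30 * 10), 1, tolerance = 0.05)
  gx <- matrix(rep(0:99, each = 80), 80, 100)
  gy <- matrix(rep(0:79, times = 100), 80, 100)
  brute <- ((gx - 49) / 30)^2 + ((gy - 39) / 10)^2 <= 1
  expect_equal(m$pixels, brute)
})

test_that("off-image seed centres error and clipped ellipses are flagged", {
  expect_error(rasterize_ellipse(list(cell_id = 7, x = 40, y = 5,
                                      radius_x = 3, radius_y = 3), c(24, 24)),
               "outside")
  expect_warning(
    m <- rasterize_ellipse(list(cell_id = 7, x = 2, y = 10,
                                radius_x = 5, radius_y = 5), c(24, 24)),
    "clipped")
  expect_true(attr(m, "clipped"))
})

test_that("active contour with zero iterations is the identity", {
  init <- rasterize_ellipse(list(cell_id = 1, x = 20, y = 20,
                                 radius_x = 6, radius_y = 6), c(40, 40))
  img <- matrix(runif(1600), 40, 40)
  out <- active_contour_refine(img, init, n_iterations = 0)
  expect_identical(out$pixels, init$pixels)
  expect_equal(formals(active_contour_refine)$n_iterations, 10)
})

test_that("the snake locks onto a high-contrast disc from an offset seed", {
  ny <- nx <- 96
  true_disc <- disc_mask(ny, nx, 48, 48, 20)
  img <- matrix(1000, ny, nx)
  img[true_disc] <- 3000
  seed <- list(cell_id = 1, x = 53, y = 48, radius_x = 18, radius_y = 18)
  init <- rasterize_ellipse(seed, c(ny, nx))
  refined <- active_contour_refine(img, init, n_iterations = 10)
  expect_gte(jaccard(refined$pixels, true_disc), 0.90)
  expect_gt(jaccard(refined$pixels, true_disc),
            jaccard(init$pixels, true_disc))
})

test_that("degenerate snake inputs raise informative errors", {
  img <- matrix(0, 20, 20)
  expect_error(active_contour_refine(img, list(pixels = img > 0)), "CellMask")
  fake <- structure(list(cell_id = 5, pixels = matrix(FALSE, 20, 20)),
                    class = "CellMask")
  expect_error(active_contour_refine(img, fake), "5")
})

test_that("thresholding matches the brute-force area-filtered count", {
  img <- matrix(0, 12, 12)
  img[3:6, 3:8] <- 100
  bw <- threshold_regions(img, 50, min_area = 1, fill_holes = FALSE)
  expect_equal(bw, img >= 50)
  expect_warning(threshold_regions(img, 101), "empty")

  set.seed(42)
  for (rep in 1:100) {
    img <- matrix(sample(c(0, 60, 100), 144, TRUE, c(0.5, 0.2, 0.3)), 12, 12)
    thr <- sample(c(50, 80), 1)
    ma <- sample(c(1, 3, 6), 1)
    bw <- suppressWarnings(
      threshold_regions(img, thr, min_area = ma, fill_holes = FALSE))
    expect_equal(sum(bw), oracle_threshold_count(img, thr, ma))
  }
})

test_that("hole filling closes enclosed background", {
  img <- matrix(0, 11, 11)
  img[3:9, 3:9] <- 100
  img[5:7, 5:7] <- 0  # a hole
  bw <- threshold_regions(img, 50, min_area = 1, fill_holes = TRUE)
  expect_true(all(bw[5:7, 5:7]))
})

test_that("watershed splits touching discs at the distance ridge", {
  ny <- nx <- 64
  d1 <- disc_mask(ny, nx, 22, 32, 12)
  d2 <- disc_mask(ny, nx, 42, 32, 12)
  region <- d1 | d2
  clicks <- data.frame(cell_id = c(1, 2), x = c(22, 42), y = c(32, 32))
  masks <- watershed_split(region, clicks)
  expect_length(masks, 2)
  expect_equal(sum(masks[[1]]$pixels & masks[[2]]$pixels), 0)
  expect_equal(masks[[1]]$pixels | masks[[2]]$pixels, region)
  expect_gte(jaccard(masks[[1]]$pixels, d1), 0.85)
  expect_gte(jaccard(masks[[2]]$pixels, d2), 0.85)
  # nearest-centre assignment oracle: every assigned pixel is no farther
  # from its own click than from the other (up to the shared ridge)
  own <- which(masks[[1]]$pixels)
  xx <- (own - 1) %/% ny; yy <- (own - 1) %% ny
  expect_true(all((xx - 22)^2 + (yy - 32)^2 <= (xx - 42)^2 + (yy - 32)^2))
})

test_that("watershed edge cases behave", {
  region <- disc_mask(32, 32, 15, 15, 8)
  one <- watershed_split(region, data.frame(cell_id = 1, x = 15, y = 15))
  expect_equal(one[[1]]$pixels, region)
  expect_error(watershed_split(region, data.frame(cell_id = 1, x = 1, y = 1)),
               "outside")
  expect_warning(
    two <- watershed_split(region, data.frame(cell_id = c(1, 2),
                                              x = c(15, 15), y = c(15, 15))),
    "collapsed")
  expect_length(two, 1)
  expect_equal(two[[1]]$cell_id, 1)
  # a second, unclicked component is left out
  region2 <- region | disc_mask(32, 32, 27, 27, 3)
  one2 <- watershed_split(region2, data.frame(cell_id = 1, x = 15, y = 15))
  expect_equal(one2[[1]]$pixels, region)
})

test_that("equivalent diameter follows the closed form", {
  m <- matrix(FALSE, 20, 20)
  m[1:10, 1:10] <- TRUE  # 100 px
  expect_equal(equivalent_diameter(m, 0.21), 2 * sqrt(100 / pi) * 0.21)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(equivalent_diameter(single, 1), 2 / sqrt(pi))
  disc <- disc_mask(128, 128, 63, 63, 50)
  expect_equal(equivalent_diameter(disc, 0.21), 21.0, tolerance = 0.02)
  expect_error(equivalent_diameter(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("jaccard equals brute-force set computation and is symmetric", {
  sq <- matrix(FALSE, 8, 8); sq[3:5, 3:5] <- TRUE
  sh <- matrix(FALSE, 8, 8); sh[3:5, 4:6] <- TRUE
  expect_equal(jaccard(sq, sq), 1)
  expect_equal(jaccard(sq, sh), 0.5)  # intersection 6, union 12
  disjoint <- matrix(FALSE, 8, 8); disjoint[7:8, 7:8] <- TRUE
  expect_equal(jaccard(sq, disjoint), 0)
  expect_error(jaccard(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)),
               "empty")
  set.seed(7)
  for (rep in 1:100) {
    a <- matrix(runif(100) < 0.4, 10, 10)
    b <- matrix(runif(100) < 0.4, 10, 10)
    if (!any(a | b)) next
    expect_equal(jaccard(a, b), oracle_jaccard(a, b))
    expect_equal(jaccard(a, b), jaccard(b, a))
  }
})

test_that("segmentation results enforce disjointness and unique ids", {
  a <- cell_mask(1, disc_mask(32, 32, 10, 10, 5))
  b <- cell_mask(2, disc_mask(32, 32, 22, 22, 5))
  res <- segmentation_result(list(a, b), "active_contour",
                             list(n_iterations = 10))
  expect_s3_class(res, "SegmentationResult")
  expect_equal(res$parameters$n_iterations, 10)
  overlap <- cell_mask(3, disc_mask(32, 32, 12, 10, 5))
  expect_error(segmentation_result(list(a, overlap)), "disjoint")
  dup <- cell_mask(1, disc_mask(32, 32, 22, 22, 5))
  expect_error(segmentation_result(list(a, dup)), "duplicate")
})

test_that("field segmentation yields disjoint single-component masks", {
  for (seed in c(21, 22)) {
    truth <- generate_population(n_cells = 6, shape = c(384, 384),
                                 rng_seed = seed)
    stack <- render_timelapse(truth, times_min = 0)
    seg <- segment_stack(stack, truth_seeds(truth))
    acc <- Reduce(`+`, lapply(seg$masks, function(m) m$pixels * 1L))
    expect_lte(max(acc), 1L)
    for (m in seg$masks)
      expect_equal(fretcell:::.n_components8(m$pixels), 1L)
  }
})

test_that("watershed output never exceeds the thresholded region", {
  truth <- generate_population(n_cells = 5, shape = c(320, 320),
                               min_gap_frac = -0.15, rng_seed = 31)
  stack <- render_timelapse(truth, times_min = 0)
  donor <- get_frame(stack, "donor", 1)
  region <- threshold_regions(donor, 200)
  clicks <- data.frame(cell_id = truth$cells$cell_id,
                       x = round(truth$cells$x), y = round(truth$cells$y))
  masks <- watershed_split(region, clicks)
  un <- Reduce(`|`, lapply(masks, function(m) m$pixels))
  expect_true(all(region[un]))  # union contained in the region
  acc <- Reduce(`+`, lapply(masks, function(m) m$pixels * 1L))
  expect_lte(max(acc), 1L)
})
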