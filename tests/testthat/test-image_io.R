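test_that("stacks round-trip bit-exactly through 16-bit TIFF", {
  truth <- generate_population(n_cells = 3, shape = c(64, 64),
                               pixel_size_um = 0.42,
                               diameter_range_um = c(6, 9), rng_seed = 11)
  stack <- render_timelapse(truth, times_min = seq(0, 30, 5))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(stack, path)
  back <- load_stack(path, pixel_size_um = 0.42)
  expect_identical(dim(back$pixels), c(64L, 64L, 4L, 7L))
  expect_equal(back$pixels, stack$pixels)
  expect_equal(back$time_points_min, stack$time_points_min)
})

test_that("a list of single-timepoint files concatenates in given order", {
  truth <- generate_population(n_cells = 2, shape = c(48, 48),
                               diameter_range_um = c(6, 8), rng_seed = 3)
  s1 <- render_timelapse(truth, times_min = 0, noise_seed = 5)
  s2 <- render_timelapse(truth, times_min = 0, noise_seed = 6)
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_stack(s1, p1)
  write_stack(s2, p2)
  both <- load_stack(c(p1, p2), time_points_min = c(0, 5))
  expect_identical(dim(both$pixels)[4], 2L)
  expect_equal(both$pixels[, , , 1], s1$pixels[, , , 1])
  expect_equal(both$pixels[, , , 2], s2$pixels[, , , 1])
})

test_that("wrong channel counts and malformed files are rejected", {
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.1, 8, 8), matrix(0.2, 8, 8),
                       matrix(0.3, 8, 8)), p)
  expect_error(load_stack(p), "channels")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(load_stack(bad), "TIFF")
})

test_that("channel reordering is a pure permutation of the planes", {
  arr <- array(sample(0:4095, 16 * 16 * 4 * 2, TRUE), c(16, 16, 4, 2))
  disk_order <- c("donor", "direct_acceptor", "brightfield", "acceptor")
  st <- image_stack(arr, pixel_size_um = 1, time_points_min = c(0, 5),
                    channel_names = disk_order)
  expect_identical(st$channel_names, fret_channels())
  # the multiset of per-plane sums is preserved
  sums_in <- sort(apply(arr, 3, sum))
  sums_out <- sort(apply(st$pixels, 3, sum))
  expect_equal(sums_out, sums_in)
  # and each named plane landed in its canonical slot
  expect_equal(st$pixels[, , 1, ], arr[, , 3, ])
  expect_equal(st$pixels[, , 2, ], arr[, , 1, ])
  expect_equal(st$pixels[, , 3, ], arr[, , 4, ])
  expect_equal(st$pixels[, , 4, ], arr[, , 2, ])
})

test_that("stack invariants are enforced", {
  arr <- array(1, c(8, 8, 4, 2))
  expect_error(image_stack(arr, 0.42, c(0, 0)), "increasing")
  expect_error(image_stack(arr, -1, c(0, 5)), "pixel_size")
  expect_error(image_stack(arr * 9999, 0.42, c(0, 5)), "12")
  expect_error(image_stack(array(1, c(8, 8, 3, 2)), 0.42, c(0, 5)),
               "channels")
})

test_that("OME-XML metadata is parsed for axes and pixel size", {
  desc <- paste0(
    '<?xml version="1.0"?><OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image><Pixels SizeX="32" SizeY="32" SizeC="4" SizeT="2" SizeZ="1"',
    ' DimensionOrder="XYCZT" PhysicalSizeX="0.21">',
    '<Channel Name="brightfield"/><Channel Name="donor"/>',
    '<Channel Name="acceptor"/><Channel Name="direct_acceptor"/>',
    '</Pixels></Image></OME>')
  ome <- fretcell:::.parse_ome(desc)
  expect_equal(ome$size_c, 4)
  expect_equal(ome$size_t, 2)
  expect_equal(ome$dimension_order, "XYCZT")
  expect_equal(ome$pixel_size_um, 0.21)
  expect_equal(ome$channel_names, fret_channels())
  expect_null(fretcell:::.parse_ome("plain description"))
})

test_that("seed files validate and default the vertical radius", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,x,y,radius_x,radius_y", "1, 50, 60, 20,"), p)
  s <- load_seeds(p)
  expect_equal(s$radius_y, 20)
  expect_equal(s$x, 50)

  writeLines(c("cell_id,x,y,radius_x", "1,5,5,4", "1,9,9,4"), p)
  expect_error(load_seeds(p), "duplicate")
  writeLines(c("cell_id,x,y,radius_x", "1,5,5,0"), p)
  expect_error(load_seeds(p), "positive")
})

test_that("trace CSVs round-trip and reject ragged inputs", {
  truth <- generate_population(n_cells = 1, shape = c(48, 48),
                               diameter_range_um = c(8, 10), rng_seed = 2)
  stack <- render_timelapse(truth, times_min = c(0, 5, 10),
                            noise = list(shot = FALSE, read_sigma = 0))
  traces <- build_traces(stack, truth$masks)
  p <- withr::local_tempfile(fileext = ".csv")
  write_traces(traces, p)
  back <- read_traces(p)
  expect_equal(nrow(back), 3)
  expect_equal(back$fret_ratio, traces[[1]]$fret_ratio, tolerance = 1e-6)
  expect_equal(back$fret_ratio_normalized[1], 1)

  ragged <- c(traces, list(within.list(traces[[1]], {
    times_min <- times_min[1:2]
    fret_ratio <- fret_ratio[1:2]
    fret_ratio_normalized <- fret_ratio_normalized[1:2]
    mean_intensity <- mean_intensity[, 1:2]
  })))
  expect_error(write_traces(ragged, p), "mixed")
  expect_error(write_traces(list(), p), "no traces")
})

test_that("boundary overlays colour the mask boundaries pixel-exactly", {
  truth <- generate_population(n_cells = 2, shape = c(64, 64),
                               diameter_range_um = c(8, 10), rng_seed = 4)
  stack <- render_timelapse(truth, times_min = 0)
  p0 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_overlay(stack, list(), p0)
  write_overlay(stack, truth$masks, p2, label = FALSE)
  plain <- png::readPNG(p0)
  over <- png::readPNG(p2)
  # no masks: a plain greyscale brightfield copy
  expect_equal(plain[, , 1], plain[, , 2])
  bf <- get_frame(stack, "brightfield", 1)
  expect_equal(plain[, , 1], (bf - min(bf)) / diff(range(bf)),
               tolerance = 1 / 255)
  # boundary pixels differ from the background rendering at those coordinates
  cols <- character(0)
  for (m in truth$masks) {
    b <- m$boundary
    idx <- cbind(b[, "y"] + 1L, b[, "x"] + 1L)
    differs <- abs(over[cbind(idx, 1)] - plain[cbind(idx, 1)]) > 1e-3 |
      abs(over[cbind(idx, 2)] - plain[cbind(idx, 2)]) > 1e-3 |
      abs(over[cbind(idx, 3)] - plain[cbind(idx, 3)]) > 1e-3
    expect_true(all(differs))
    cols <- c(cols, grDevices::rgb(over[cbind(idx, 1)], over[cbind(idx, 2)],
                                   over[cbind(idx, 3)]))
  }
  # two masks give at least two distinct non-background boundary colours
  expect_gte(length(unique(cols)), 2)
  # a mask with the wrong extent is rejected
  small <- cell_mask(9, matrix(c(TRUE, rep(FALSE, 8)), 3, 3), check = FALSE)
  expect_error(write_overlay(stack, list(small), p2), "extent")
})

test_that("mask label images round-trip", {
  truth <- generate_population(n_cells = 3, shape = c(48, 48),
                               pixel_size_um = 1,
                               diameter_range_um = c(6, 9), rng_seed = 8)
  p <- withr::local_tempfile(fileext = ".tif")
  write_mask_labels(truth$masks, p)
  back <- read_mask_labels(p)
  expect_equal(length(back), 3)
  for (i in 1:3) expect_equal(back[[i]]$pixels, truth$masks[[i]]$pixels)
})
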