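test_that("the mean-diameter split partitions cells with ties going large", {
  rec <- data.frame(cell_id = 1:4, diameter_um = c(10, 20, 30, 40))
  sp <- split_by_mean_diameter(rec)
  expect_setequal(sp$small$diameter_um, c(10, 20))
  expect_setequal(sp$large$diameter_um, c(30, 40))
  expect_equal(sp$mean_diameter_um, 25)

  sp2 <- split_by_mean_diameter(data.frame(diameter_um = c(10, 30)))
  expect_equal(sp2$small$diameter_um, 10)
  expect_equal(sp2$large$diameter_um, 30)

  # a cell exactly at the mean is "large"
  sp3 <- split_by_mean_diameter(data.frame(diameter_um = c(10, 20, 30)))
  expect_true(20 %in% sp3$large$diameter_um)

  expect_warning(split_by_mean_diameter(data.frame(diameter_um = c(5, 5))),
                 "identical")
  expect_error(split_by_mean_diameter(data.frame(diameter_um = 5)),
               "2 records")
})

test_that("the pooled t-test matches the closed-form oracle", {
  same <- c(1, 2, 3)
  tt <- two_sample_t(same, same)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_false(tt$significant)

  a <- 1:5; b <- 2:6
  tt <- two_sample_t(a, b)
  or <- oracle_t(a, b)
  expect_equal(tt$statistic, or$statistic)
  expect_equal(tt$p_value, or$p_value)

  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
  expect_error(two_sample_t(c(2, 2), c(2, 2)), "pooled variance")

  set.seed(19)
  for (rep in 1:100) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), 0.5)
    tt <- two_sample_t(a, b)
    or <- oracle_t(a, b)
    expect_equal(tt$statistic, or$statistic)
    expect_equal(tt$p_value, or$p_value)
    # symmetry up to the statistic's sign
    rev <- two_sample_t(b, a)
    expect_equal(rev$statistic, -tt$statistic)
    expect_equal(rev$p_value, tt$p_value)
  }
})

test_that("the KS statistic is the brute-force ECDF supremum", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:4, 11:14)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 3))$statistic, 0.5)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")

  set.seed(23)
  for (rep in 1:100) {
    a <- rnorm(sample(4:15, 1)); b <- rnorm(sample(4:15, 1), 0.3)
    ks <- ks_two_sample(a, b)
    expect_equal(ks$statistic, oracle_ks_d(a, b))
    expect_equal(ks_two_sample(b, a)$statistic, ks$statistic)
    expect_equal(ks_two_sample(b, a)$p_value, ks$p_value)
  }
})

test_that("pearson matches the definitional formula and returns the fit", {
  x <- c(1, 2, 3, 4)
  p <- pearson(x, 2 * x)
  expect_equal(p$r, 1)
  expect_equal(p$slope, 2)
  expect_equal(p$intercept, 0)
  expect_equal(pearson(x, -x + 7)$r, -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson(1:2, 1:2), "length")

  set.seed(29)
  for (rep in 1:100) {
    x <- rnorm(sample(5:20, 1))
    y <- 0.5 * x + rnorm(length(x))
    expect_equal(pearson(x, y)$r, oracle_pearson(x, y))
  }
})

test_that("the KDE is a normalized non-negative density", {
  set.seed(31)
  v <- rnorm(40, 10, 2)
  bw <- bw.nrd0(v)
  grid <- seq(min(v) - 4 * bw, max(v) + 4 * bw, length.out = 512)
  k <- kde(v, eval_grid = grid)
  expect_true(all(k$density >= 0))
  integral <- sum(diff(grid) * (head(k$density, -1) + tail(k$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 0.01)

  # two well-separated values: bimodal with modes near the values
  k2 <- kde(c(0, 10))
  peaks <- k2$grid[which(diff(sign(diff(k2$density))) == -2) + 1]
  expect_length(peaks, 2)
  expect_lt(abs(peaks[1] - 0), 1)
  expect_lt(abs(peaks[2] - 10), 1)
  expect_error(kde(5), "2 values")
})

test_that("population_stats summarises groups, tests and correlation", {
  set.seed(37)
  n <- 60
  d <- runif(n, 15, 45)
  rec <- data.frame(cell_id = seq_len(n), diameter_um = d,
                    total_relative_change = 0.4 - 0.008 * d + rnorm(n, 0, 0.03),
                    condition = rep(c("insulin", "basal"), each = n / 2))
  rec$total_relative_change[rec$condition == "basal"] <- rnorm(n / 2, 0, 0.03)
  ps <- population_stats(rec)
  expect_setequal(ps$groups$group[1:2], c("small", "large"))
  expect_equal(ps$groups$mean_normalized[1], 1)
  expect_true(all(c("small_vs_large_t", "small_vs_large_ks",
                    "basal_vs_insulin_t", "basal_vs_insulin_ks") %in%
                    ps$tests$comparison))
  expect_true(is.finite(ps$correlation$r))
  expect_error(population_stats(rec[, 1:2]), "column")
})
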