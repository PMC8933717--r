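# Population-level analyses of per-cell measurements: size splits at the
# mean diameter, pooled-variance t-tests, two-sample Kolmogorov-Smirnov
# tests, Pearson correlation with a free linear fit, and Gaussian kernel
# density estimates of response distributions.

#' Split cell records at the mean diameter
#'
#' Cells with diameter strictly below the population mean form the "small"
#' group; cells at or above the mean the "large" group (ties at the mean go
#' to large). The partition is exhaustive and disjoint.
#'
#' @param records `data.frame` with a `diameter_um` column, >= 2 rows.
#' @return List with elements `small` and `large` (subsets of `records`) and
#'   `mean_diameter_um`.
#' @export
split_by_mean_diameter <- function(records) {
  if (nrow(records) < 2) .stopf("need at least 2 records to split")
  m <- mean(records$diameter_um)
  if (stats::sd(records$diameter_um) == 0)
    .warnf("all diameters identical: every cell falls in the 'large' group by the tie rule")
  list(small = records[records$diameter_um < m, , drop = FALSE],
       large = records[records$diameter_um >= m, , drop = FALSE],
       mean_diameter_um = m)
}

#' Two-sample pooled-variance Student's t-test
#'
#' Two-sided test comparing group means with the classical pooled standard
#' deviation. Significance is called at p < 0.05.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @return List with `statistic`, `p_value`, `df`, `significant`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    .stopf("each sample needs at least 2 values")
  pooled <- ((length(a) - 1) * stats::var(a) +
             (length(b) - 1) * stats::var(b)) / (length(a) + length(b) - 2)
  if (pooled == 0) .stopf("zero pooled variance: t-test undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), significant = ht$p.value < 0.05)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two empirical distributions via the supremum distance between
#' their ECDFs, with the asymptotic two-sided p-value. Significance is
#' called at p < 0.05.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `statistic` (D), `p_value`, `significant`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) .stopf("samples must be non-empty")
  ht <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < 0.05)
}

#' Pearson correlation with a free linear fit
#'
#' Sample Pearson correlation between two per-cell measurements, plus the
#' ordinary least-squares line (slope, intercept) for plotting.
#'
#' @param x,y Equal-length numeric vectors, length >= 3, both non-constant.
#' @return List with `r`, `slope`, `intercept`, `p_value` (two-sided test of
#'   zero correlation).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    .stopf("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stopf("correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), p_value = ct$p.value)
}

#' Gaussian kernel density estimate on a grid
#'
#' Density of per-cell values smoothed with a Gaussian kernel; bandwidth
#' defaults to Silverman's rule of thumb. The default grid spans the data
#' range extended by 3 bandwidths, at 256 points.
#'
#' @param values Numeric vector, length >= 2.
#' @param eval_grid Optional evaluation grid; defaults as above.
#' @param bw Kernel bandwidth; default `stats::bw.nrd0(values)`.
#' @param n_grid Number of default grid points.
#' @return `data.frame` with columns `grid` and `density`.
#' @export
kde <- function(values, eval_grid = NULL, bw = NULL, n_grid = 256) {
  if (length(values) < 2) .stopf("need at least 2 values for a KDE")
  if (is.null(bw)) bw <- stats::bw.nrd0(values)
  if (is.null(eval_grid))
    eval_grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw,
                     length.out = n_grid)
  dens <- vapply(eval_grid,
                 function(g) mean(stats::dnorm(g, mean = values, sd = bw)),
                 numeric(1))
  data.frame(grid = eval_grid, density = dens)
}

#' Population summary of size-dependent responses
#'
#' Reproduces the standard analysis of a stimulated field: split cells at
#' the mean diameter, compare small vs large response means (pooled t-test)
#' and distributions (KS test), correlate diameter with response, and report
#' group means normalized to the small group. When a `condition` column with
#' two levels is present, the same comparisons are additionally run between
#' conditions.
#'
#' @param records `data.frame` with `cell_id`, `diameter_um`, a response
#'   column, and optionally `condition`.
#' @param response Name of the response column (default
#'   `"total_relative_change"`).
#' @return List with `groups` (per-group n/mean/SE summary `data.frame`),
#'   `tests` (one row per comparison: statistic, p, significance), and
#'   `correlation` (output of [pearson()] on diameter vs response).
#' @export
population_stats <- function(records, response = "total_relative_change") {
  if (!response %in% names(records))
    .stopf("records lack a '%s' column", response)
  y <- records[[response]]
  sp <- split_by_mean_diameter(records)
  grp <- function(label, v) data.frame(
    group = label, n = length(v), mean = mean(v),
    se = stats::sd(v) / sqrt(length(v)))
  groups <- rbind(grp("small", sp$small[[response]]),
                  grp("large", sp$large[[response]]))
  groups$mean_normalized <- groups$mean / groups$mean[1]
  tt <- two_sample_t(sp$small[[response]], sp$large[[response]])
  ks <- ks_two_sample(sp$small[[response]], sp$large[[response]])
  tests <- data.frame(
    comparison = c("small_vs_large_t", "small_vs_large_ks"),
    statistic = c(tt$statistic, ks$statistic),
    p_value = c(tt$p_value, ks$p_value),
    significant = c(tt$significant, ks$significant))
  if ("condition" %in% names(records) &&
      length(unique(records$condition)) == 2) {
    lv <- sort(unique(records$condition))
    ya <- y[records$condition == lv[1]]
    yb <- y[records$condition == lv[2]]
    tt2 <- two_sample_t(ya, yb)
    ks2 <- ks_two_sample(ya, yb)
    groups <- rbind(groups, grp(lv[1], ya)[, names(groups)[1:4]] |>
                      transform(mean_normalized = NA_real_),
                    grp(lv[2], yb)[, names(groups)[1:4]] |>
                      transform(mean_normalized = NA_real_))
    tests <- rbind(tests, data.frame(
      comparison = c(sprintf("%s_vs_%s_t", lv[1], lv[2]),
                     sprintf("%s_vs_%s_ks", lv[1], lv[2])),
      statistic = c(tt2$statistic, ks2$statistic),
      p_value = c(tt2$p_value, ks2$p_value),
      significant = c(tt2$significant, ks2$significant)))
  }
  corr <- pearson(records$diameter_um, y)
  list(groups = groups, tests = tests, correlation = corr,
       mean_diameter_um = sp$mean_diameter_um)
}
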