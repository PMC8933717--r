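# Exponential uptake-kinetics fitting. After stimulation the normalized FRET
# ratio of a responding cell rises to a plateau; the relative change
# dF(t) = F_norm(t) - 1 is fitted with the rise-to-plateau model
#   dF(t) = F_final * (1 - exp(-k_u * t))
# where F_final is the asymptotic relative change and k_u (1/min) the uptake
# rate. Fits with R^2 below a quality threshold are discarded.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of fitted against observed values. Undefined for a
#' constant observed series (zero total sum of squares).
#'
#' @param observed,fitted Equal-length numeric vectors (length >= 2).
#' @return R-squared (<= 1; can be negative for fits worse than the mean).
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2)
    .stopf("observed and fitted must have equal length >= 2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    .stopf("R-squared undefined: observed values are constant")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Fit the exponential uptake model to one normalized trace
#'
#' Bounded nonlinear least squares of `F_final * (1 - exp(-k_u * t))`
#' against the relative-change trace `normalized - normalized[1]`. Start
#' values: `F_final` at the last relative change, `k_u` at 1 over the
#' recording duration; bounds `F_final` in (-1, 5), `k_u` in [0, 10] per
#' minute.
#'
#' @param normalized Normalized FRET trace (first value 1), length >= 3.
#' @param times_min Acquisition times in minutes, starting at 0.
#' @param cell_id Optional label carried into the result.
#' @param r2_threshold Keep threshold on R-squared (default 0.8; fits with
#'   R-squared strictly below it are marked discarded).
#' @return An `ExpFit`: one-row `data.frame` with `cell_id`, `f_final`,
#'   `k_u_per_min`, `r_squared`, `converged`, `kept`.
#' @export
fit_uptake <- function(normalized, times_min, cell_id = NA,
                       r2_threshold = 0.8) {
  if (length(normalized) < 3) .stopf("need at least 3 timepoints to fit")
  if (length(times_min) != length(normalized))
    .stopf("times and trace lengths differ")
  if (abs(times_min[1]) > 1e-9) .stopf("times must start at 0")
  df_rel <- normalized - normalized[1]
  t <- times_min

  if (all(abs(df_rel - df_rel[1]) < 1e-12)) {
    # flat trace: the model fits it exactly with F_final = 0 but R^2 is
    # undefined, so the fit can never pass the quality filter
    return(data.frame(cell_id = cell_id, f_final = 0, k_u_per_min = 0,
                      r_squared = NA_real_, converged = TRUE, kept = FALSE))
  }

  start <- list(A = df_rel[length(df_rel)], k = 1 / max(t))
  start$A <- min(max(start$A, -0.9), 4.9)
  fit <- tryCatch(
    minpack.lm::nlsLM(df_rel ~ A * (1 - exp(-k * t)),
                      start = start, lower = c(A = -0.999, k = 0),
                      upper = c(A = 5, k = 10),
                      control = minpack.lm::nls.lm.control(
                        ptol = 1e-10, ftol = 1e-10, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(cell_id = cell_id, f_final = NA_real_,
                      k_u_per_min = NA_real_, r_squared = NA_real_,
                      converged = FALSE, kept = FALSE))
  }
  co <- stats::coef(fit)
  r2 <- r_squared(df_rel, stats::fitted(fit))
  data.frame(cell_id = cell_id, f_final = unname(co["A"]),
             k_u_per_min = unname(co["k"]), r_squared = r2,
             converged = TRUE,
             kept = !is.na(r2) && r2 >= r2_threshold)
}

#' Fit uptake kinetics for every cell trace
#'
#' @param traces List of `CellTrace` objects from [build_traces()].
#' @param r2_threshold Keep threshold on R-squared (default 0.8).
#' @return `data.frame` with one `ExpFit` row per cell plus `diameter_um`.
#' @export
fit_cells <- function(traces, r2_threshold = 0.8) {
  if (!length(traces)) .stopf("no traces to fit")
  do.call(rbind, lapply(traces, function(tr) {
    f <- fit_uptake(tr$fret_ratio_normalized, tr$times_min,
                    cell_id = tr$cell_id, r2_threshold = r2_threshold)
    cbind(f[1], diameter_um = tr$diameter_um, f[-1])
  }))
}

#' Filter fits by quality
#'
#' Keeps converged fits whose R-squared is at or above the threshold; the
#' discard rule is strictly "lower than", so R-squared exactly at the
#' threshold is kept.
#'
#' @param fits `data.frame` of `ExpFit` rows.
#' @param threshold R-squared cutoff (default 0.8).
#' @return The kept subset of `fits`.
#' @export
filter_fits <- function(fits, threshold = 0.8) {
  keep <- fits$converged & !is.na(fits$r_squared) &
    fits$r_squared >= threshold
  fits[keep, , drop = FALSE]
}
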