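# Quantifies CaV2.1 inactivation from 3 s sweeps: percent inactivation at
# the end of the pulse and the single-exponential decay time constant.

# crude noise-SD estimate from first differences (decay contributes little
# at typical sampling rates)
estimate_noise_sd <- function(current) {
  stats::sd(diff(current)) / sqrt(2)
}

#' Degree of inactivation at the end of a long pulse
#'
#' Computes \eqn{100 (1 - I_{end}/I_{peak})}, clipped to \[0, 100\], where
#' `I_end` is the mean current over the final `end_window_ms` of the sweep
#' and `I_peak` is the most-negative value of the `peak_window_ms` running
#' mean of the trace. Both statistics are window averages so that neither
#' is biased by the noise floor: a raw single-sample extremum over a long,
#' slowly decaying trace systematically overestimates small peak currents
#' (extreme-value bias), which would inflate the apparent inactivation of
#' low-density conditions.
#'
#' @param sweep A 3 s `sweep` with a detectable inward peak.
#' @param end_window_ms Averaging window at the pulse end (ms).
#' @param peak_window_ms Running-mean window for the peak estimate (ms);
#'   defaults to `end_window_ms`. Must stay well below the inactivation
#'   time constant.
#' @param blank_ms Blanking window for peak detection (ms).
#' @return Degree of inactivation in percent, in \[0, 100\].
#' @export
percent_inactivation <- function(sweep, end_window_ms = 50,
                                 peak_window_ms = end_window_ms,
                                 blank_ms = 1) {
  if (length(sweep$current_pA) == 0) stop("empty sweep", call. = FALSE)
  noise <- estimate_noise_sd(sweep$current_pA)
  i_peak <- smoothed_peak(sweep, peak_window_ms, blank_ms)
  if (i_peak >= 0 || abs(i_peak) < 3 * noise)
    stop("unreliable measurement: peak current below noise floor",
         call. = FALSE)
  t_end <- max(sweep$time_ms)
  tail_idx <- sweep$time_ms >= t_end - end_window_ms
  i_end <- mean(sweep$current_pA[tail_idx])
  min(100, max(0, 100 * (1 - i_end / i_peak)))
}

# most-negative value of the centered running mean of the trace
smoothed_peak <- function(sweep, window_ms, blank_ms) {
  tt <- sweep$time_ms
  cur <- sweep$current_pA
  dt <- tt[2] - tt[1]
  w <- max(1L, round(window_ms / dt))
  sm <- if (w > 1 && w < length(cur))
    stats::filter(cur, rep(1 / w, w), sides = 2) else cur
  ok <- !is.na(sm) & tt > blank_ms
  min(sm[ok])
}

# profiled RSS for I(t) = A exp(-(t - t0)/tau) + C: A and C by linear least
# squares given tau
exp_profiled_rss <- function(tau, tt, y) {
  x <- exp(-(tt - tt[1]) / tau)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(rss = sum(fit$residuals^2), C = fit$coefficients[1],
       A = fit$coefficients[2])
}

#' Single-exponential fit of the inactivation phase
#'
#' Fits \eqn{I(t) = A e^{-(t - t_{peak})/\tau} + C} by least squares from the
#' peak sample to the pulse end. `A` and `C` are profiled out linearly; the
#' time constant is located by a coarse logarithmic scan followed by golden
#' -section refinement ([stats::optimize()]) within the bracketing interval.
#'
#' @param sweep A 3 s `sweep`; requires a decay phase
#'   (degree of inactivation > 5%).
#' @param blank_ms Blanking window for peak detection (ms).
#' @return An `inactivation_result`: list with `test_voltage`, `degree_pct`,
#'   `tau_ms`, `pedestal_fraction` (C / I_peak), `fit_window` (ms),
#'   `converged`.
#' @export
fit_inactivation_tau <- function(sweep, blank_ms = 1) {
  degree <- percent_inactivation(sweep, blank_ms = blank_ms)
  if (degree <= 5)
    stop("no decay phase: degree of inactivation <= 5%", call. = FALSE)
  peak <- detect_peak_current(sweep, blank_ms)
  t_peak <- attr(peak, "time_ms")
  sel <- sweep$time_ms >= t_peak
  tt <- sweep$time_ms[sel]
  y <- sweep$current_pA[sel]
  t_end <- max(tt)

  # bracket the optimum on a log-spaced tau grid, then refine
  grid <- exp(seq(log(1), log(10 * (t_end - t_peak)), length.out = 40))
  rss_grid <- vapply(grid, function(tau) exp_profiled_rss(tau, tt, y)$rss, 0)
  ib <- which.min(rss_grid)
  lo <- grid[max(1, ib - 1)]
  hi <- grid[min(length(grid), ib + 1)]
  converged <- TRUE
  opt <- tryCatch(
    stats::optimize(function(ltau) exp_profiled_rss(exp(ltau), tt, y)$rss,
                    interval = log(c(lo, hi)), tol = 1e-10),
    error = function(e) NULL)
  if (is.null(opt)) {
    converged <- FALSE
    tau <- grid[ib]
  } else tau <- exp(opt$minimum)
  pr <- exp_profiled_rss(tau, tt, y)
  structure(list(test_voltage = sweep$test_voltage, degree_pct = degree,
                 tau_ms = tau,
                 pedestal_fraction = as.numeric(pr$C / as.numeric(peak)),
                 fit_window = c(t_peak, t_end), rss = pr$rss,
                 converged = converged),
            class = "inactivation_result")
}

#' @export
print.inactivation_result <- function(x, ...) {
  cat(sprintf(
    "Inactivation at %+g mV: %.1f%% at pulse end, tau %.0f ms (pedestal %.2f)%s\n",
    x$test_voltage, x$degree_pct, x$tau_ms, x$pedestal_fraction,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Per-cell inactivation analysis of a recorded group
#'
#' Cells whose long-pulse peak current falls below the noise floor (an
#' unreliable measurement, possible for very low-density conditions) are
#' kept in the table with `measurable = FALSE` and `NA` measurements, the
#' in-silico counterpart of excluding unrecordable cells; group means
#' should be taken over measurable cells (`na.rm = TRUE`).
#'
#' @param recordings List of `cell_recording` objects.
#' @param test_voltage Long-pulse voltage to analyse (mV; 0 or +20).
#' @return data.frame with one row per cell: `cell_id`, `degree_pct`,
#'   `tau_ms`, `converged`, `measurable`.
#' @export
analyze_inactivation_group <- function(recordings, test_voltage) {
  rows <- lapply(recordings, function(rec) {
    sw <- Filter(function(s) s$protocol_name == "inact_3s" &&
                   s$test_voltage == test_voltage, rec$sweeps)
    if (length(sw) == 0)
      stop("incomplete recording: no 3 s sweep at ", test_voltage, " mV",
           call. = FALSE)
    res <- tryCatch(fit_inactivation_tau(sw[[1]]), error = function(e) {
      if (grepl("unreliable measurement", conditionMessage(e))) NULL
      else stop(e)
    })
    if (is.null(res))
      data.frame(cell_id = rec$cell_id, degree_pct = NA_real_,
                 tau_ms = NA_real_, converged = NA, measurable = FALSE)
    else
      data.frame(cell_id = rec$cell_id, degree_pct = res$degree_pct,
                 tau_ms = res$tau_ms, converged = res$converged,
                 measurable = TRUE)
  })
  do.call(rbind, rows)
}
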