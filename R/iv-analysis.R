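# From sweeps to I-V curves to Boltzmann-ohmic fits: peak detection,
# current-density normalization, nonlinear least-squares fitting of
# I(V) = Gmax (V - Vrev) / (1 + exp(-(V - V1/2)/k)), and group V1/2 shifts.

#' Detect the peak (maximal inward) current of a sweep
#'
#' Returns the most negative sample after the blanking window, sign
#' preserved (inward currents are negative by convention). For an
#' all-positive (outward) trace the minimum is still returned and the
#' result carries attribute `no_inward_current = TRUE`.
#' Ties break to the earliest sample.
#'
#' @param sweep A `sweep` object.
#' @param blank_ms Initial blanking window excluded from the search (ms);
#'   guards against capacitive-transient artifacts in imported data.
#' @return Peak current (pA, signed), with attributes `time_ms` (sample
#'   time) and `no_inward_current`.
#' @export
detect_peak_current <- function(sweep, blank_ms = 1) {
  stopifnot(inherits(sweep, "sweep"))
  if (length(sweep$current_pA) == 0)
    stop("empty sweep", call. = FALSE)
  if (max(sweep$time_ms) <= blank_ms)
    stop("sweep shorter than the blanking window", call. = FALSE)
  keep <- sweep$time_ms > blank_ms
  cur <- sweep$current_pA[keep]
  tt <- sweep$time_ms[keep]
  i <- which.min(cur)              # which.min takes the first minimum
  structure(cur[i], time_ms = tt[i], no_inward_current = cur[i] >= 0)
}

#' Current density
#'
#' @param peak_pA Peak current (pA).
#' @param capacitance_pF Membrane capacitance (pF, > 0).
#' @return Current density (pA/pF).
#' @export
current_density <- function(peak_pA, capacitance_pF) {
  if (!is.numeric(capacitance_pF) || any(capacitance_pF <= 0))
    stop("capacitance must be > 0", call. = FALSE)
  peak_pA / capacitance_pF
}

#' Build a current density-voltage (I-V) curve from a recording
#'
#' One point per I-V-protocol test voltage: peak current detected per sweep
#' and normalized by the cell capacitance. Points are in ascending voltage
#' order.
#'
#' @param recording A `cell_recording`.
#' @param blank_ms Blanking window passed to [detect_peak_current()].
#' @return An `iv_curve`: data.frame with columns `voltage_mV`,
#'   `density_pA_pF`; attributes `normalized` (FALSE) and `cell_id`.
#' @export
build_iv_curve <- function(recording, blank_ms = 1) {
  stopifnot(inherits(recording, "cell_recording"))
  ivs <- Filter(function(s) s$protocol_name == "iv_20ms", recording$sweeps)
  if (length(ivs) == 0)
    stop("incomplete recording: no iv_20ms sweeps", call. = FALSE)
  v <- vapply(ivs, function(s) s$test_voltage, 0)
  dens <- vapply(ivs, function(s)
    current_density(as.numeric(detect_peak_current(s, blank_ms)),
                    recording$capacitance_pF), 0)
  o <- order(v)
  new_iv_curve(v[o], dens[o], normalized = FALSE,
               cell_id = recording$cell_id)
}

new_iv_curve <- function(voltage_mV, density_pA_pF, normalized, cell_id) {
  structure(data.frame(voltage_mV = voltage_mV,
                       density_pA_pF = density_pA_pF),
            normalized = normalized, cell_id = cell_id,
            class = c("iv_curve", "data.frame"))
}

#' Normalize an I-V curve to its peak density
#'
#' Divides every density by max |density|, so the peak maps to -1 for
#' inward currents. Idempotent; the sign pattern is preserved.
#'
#' @param curve An `iv_curve`.
#' @return The normalized `iv_curve`.
#' @export
normalize_iv <- function(curve) {
  stopifnot(inherits(curve, "iv_curve"))
  m <- max(abs(curve$density_pA_pF))
  if (m == 0)
    stop("degenerate curve: all densities are zero", call. = FALSE)
  new_iv_curve(curve$voltage_mV, curve$density_pA_pF / m,
               normalized = TRUE, cell_id = attr(curve, "cell_id"))
}

# model evaluation and profiled residual sum of squares: for fixed
# (v_half, k, v_rev) the model is linear in g_max, so g_max is solved by
# linear least squares and the optimizer only searches the 3 shape
# parameters
boltzmann_shape <- function(v, v_half, k, v_rev) {
  (v - v_rev) / (1 + exp(-(v - v_half) / k))
}

profiled_rss <- function(theta, v, y) {
  f <- boltzmann_shape(v, theta[1], theta[2], theta[3])
  den <- sum(f * f)
  g <- if (den == 0) 0 else sum(f * y) / den
  list(rss = sum((y - g * f)^2), g_max = g)
}

#' Fit the Boltzmann-ohmic equation to an I-V curve
#'
#' Unweighted least-squares fit of
#' \eqn{I(V) = G_{max}(V - V_{rev})/(1 + e^{-(V - V_{1/2})/k})}
#' over the curve's (voltage, density) points. `g_max` is profiled out
#' analytically (the model is linear in it); `v_half`, `k` and `v_rev` are
#' optimized by bounded quasi-Newton (L-BFGS-B). Initialization: `v_rev`
#' from the interpolated zero crossing beyond the peak (fallback +60 mV),
#' `v_half` from the half-peak voltage on the rising limb, `k` = 5 mV.
#' Bounds: `k` in \[0.5, 20\], `v_rev` in \[20, 90\], `v_half` in
#' \[-40, 30\] mV.
#'
#' @param curve An `iv_curve` with at least 6 points spanning both sides of
#'   the peak.
#' @return A `boltzmann_fit`: list with `g_max`, `v_rev`, `v_half`, `k`,
#'   `rss`, `converged`, `n_iter`. Non-convergence is reported via
#'   `converged = FALSE`, never silently.
#' @export
fit_boltzmann_iv <- function(curve) {
  stopifnot(inherits(curve, "iv_curve"))
  v <- curve$voltage_mV
  y <- curve$density_pA_pF
  if (all(y == 0))
    stop("degenerate curve: all densities are zero", call. = FALSE)
  ipk <- which.min(y)
  if (length(v) < 6 || ipk == 1 || ipk == length(v))
    stop("need >= 6 points spanning both sides of the peak", call. = FALSE)

  # v_rev init: first upward zero crossing beyond the peak, interpolated
  v_rev0 <- 60
  post <- seq(ipk, length(v))
  zc <- which(y[post][-length(post)] < 0 & y[post][-1] >= 0)
  if (length(zc) > 0) {
    i1 <- post[zc[1]]; i2 <- i1 + 1
    v_rev0 <- v[i1] + (0 - y[i1]) * (v[i2] - v[i1]) / (y[i2] - y[i1])
  }
  # v_half init: voltage at half of peak magnitude on the rising limb
  half <- y[ipk] / 2
  pre <- seq_len(ipk)
  cross <- which(y[pre][-1] <= half & y[pre][-length(pre)] > half)
  v_half0 <- if (length(cross) > 0) {
    i1 <- cross[1]; i2 <- i1 + 1
    v[i1] + (half - y[i1]) * (v[i2] - v[i1]) / (y[i2] - y[i1])
  } else v[ipk] - 10
  lower <- c(-40, 0.5, 20)
  upper <- c(30, 20, 90)
  start <- pmin(pmax(c(v_half0, 5, v_rev0), lower), upper)

  opt <- stats::optim(start, function(th) profiled_rss(th, v, y)$rss,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e4))
  pr <- profiled_rss(opt$par, v, y)
  structure(list(g_max = pr$g_max, v_rev = opt$par[3], v_half = opt$par[1],
                 k = opt$par[2], rss = pr$rss,
                 converged = opt$convergence == 0,
                 n_iter = opt$counts[["function"]]),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "Boltzmann I-V fit: V1/2 %+.2f mV, k %.2f mV, Vrev %+.1f mV, Gmax %.3g (rss %.3g)%s\n",
    x$v_half, x$k, x$v_rev, x$g_max, x$rss,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Shift in half-activation voltage between two fitted groups
#'
#' @param group_a,group_b Lists of `boltzmann_fit` objects (e.g. control
#'   and treated). Non-converged fits are excluded and counted.
#' @return List with `shift_mV` = mean(b) - mean(a), per-group summaries
#'   (n used, n excluded, mean, sd, sem of `v_half`).
#' @export
v_half_shift <- function(group_a, group_b) {
  take <- function(g, label) {
    conv <- vapply(g, function(f) isTRUE(f$converged), NA)
    if (!any(conv))
      stop("no converged fits in group ", label, call. = FALSE)
    x <- vapply(g[conv], function(f) f$v_half, 0)
    list(v = x, n = sum(conv), excluded = sum(!conv),
         mean = mean(x), sd = stats::sd(x),
         sem = stats::sd(x) / sqrt(sum(conv)))
  }
  a <- take(group_a, "a")
  b <- take(group_b, "b")
  list(shift_mV = b$mean - a$mean,
       group_a = a[c("n", "excluded", "mean", "sd", "sem")],
       group_b = b[c("n", "excluded", "mean", "sd", "sem")])
}

#' Per-cell I-V analysis of a recorded group
#'
#' Convenience wrapper: builds each cell's density I-V curve, records the
#' peak density and its voltage, and fits the Boltzmann-ohmic equation.
#'
#' @param recordings List of `cell_recording` objects.
#' @return data.frame with one row per cell: `cell_id`, `peak_density_pA_pF`,
#'   `peak_voltage_mV`, `v_half`, `k`, `v_rev`, `g_max`, `converged`; the
#'   list of fits is attached as attribute `fits`.
#' @export
analyze_iv_group <- function(recordings) {
  rows <- lapply(recordings, function(rec) {
    curve <- build_iv_curve(rec)
    ipk <- which.min(curve$density_pA_pF)
    fit <- fit_boltzmann_iv(curve)
    list(row = data.frame(cell_id = rec$cell_id,
                          peak_density_pA_pF = curve$density_pA_pF[ipk],
                          peak_voltage_mV = curve$voltage_mV[ipk],
                          v_half = fit$v_half, k = fit$k, v_rev = fit$v_rev,
                          g_max = fit$g_max, converged = fit$converged),
         fit = fit)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(out, "fits") <- lapply(rows, `[[`, "fit")
  out
}
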