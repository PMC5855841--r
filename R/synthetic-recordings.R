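# Seeded generator of synthetic whole-cell voltage-clamp recordings:
# step I-V (20 ms) and long (3 s) inactivation protocols for cells sampled
# from a condition preset.

#' Voltage-clamp protocols
#'
#' `iv_protocol()`: 20 ms depolarizing steps from a -80 mV holding potential
#' (default -50..+60 mV in 5 mV increments, 20 kHz sampling).
#' `inactivation_protocol()`: 3 s pulses from -80 mV to +20 and 0 mV
#' (1 kHz sampling).
#'
#' @param test_voltages Step potentials (mV); strictly increasing for the
#'   I-V protocol.
#' @param duration Pulse duration (ms).
#' @param sample_rate Sampling rate (kHz).
#' @return An object of class `vc_protocol`.
#' @export
iv_protocol <- function(test_voltages = seq(-50, 60, by = 5),
                        duration = 20, sample_rate = 20) {
  if (is.unsorted(test_voltages, strictly = TRUE))
    stop("I-V test voltages must be strictly increasing", call. = FALSE)
  new_protocol("iv_20ms", test_voltages, duration, sample_rate)
}

#' @rdname iv_protocol
#' @export
inactivation_protocol <- function(test_voltages = c(0, 20),
                                  duration = 3000, sample_rate = 1) {
  new_protocol("inact_3s", test_voltages, duration, sample_rate)
}

new_protocol <- function(name, test_voltages, duration, sample_rate) {
  stopifnot(length(test_voltages) >= 1, duration > 0, sample_rate > 0)
  structure(list(name = name, holding = -80, test_voltages = test_voltages,
                 duration = duration, sample_rate = sample_rate),
            class = "vc_protocol")
}

#' @export
print.vc_protocol <- function(x, ...) {
  cat(sprintf("Protocol %s: hold %d mV, %g ms steps to [%s] mV @ %g kHz\n",
              x$name, x$holding, x$duration,
              paste(x$test_voltages, collapse = ", "), x$sample_rate))
  invisible(x)
}

# run code with a local RNG state, restoring the caller's state afterwards
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# lognormal draw parameterized by arithmetic mean and CV; cv = 0 degenerates
# to the mean
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Sample one cell from a condition preset
#'
#' Realizes between-cell variability: the peak-density magnitude is drawn
#' lognormally around the preset mean (keeping densities negative), the
#' activation midpoint and inactivation degrees normally, the inactivation
#' time constants lognormally, and the membrane capacitance lognormally
#' around 12 pF (CV 0.3). The cell conductance density is set so that the
#' noiseless steady-state peak current density equals the sampled target.
#'
#' @param preset A [condition_preset()].
#' @param seed Integer seed; the draw is a pure function of (preset, seed).
#' @return List with `params` (cell-level [gating_params()]),
#'   `capacitance_pF`, `peak_density_target` (pA/pF) and `seed`.
#' @export
sample_cell <- function(preset, seed) {
  stopifnot(inherits(preset, "condition_preset"))
  vb <- preset$variability
  g0 <- preset$gating
  with_local_seed(seed, {
    target_mag <- rlnorm_mean_cv(1, abs(preset$mean_peak_density),
                                 vb$peak_density_cv)
    v_half <- stats::rnorm(1, g0$v_half_act, vb$v_half_sd_mV)
    inact <- g0$inact
    inact$degree_pct <- pmin(100, pmax(
      0, stats::rnorm(nrow(inact), inact$degree_pct, vb$degree_sd_pct)))
    inact$tau_ms <- vapply(inact$tau_ms, function(tau)
      rlnorm_mean_cv(1, tau, vb$tau_cv), 0)
    cap <- rlnorm_mean_cv(1, 12, 0.3)
    inact$pedestal_r <- vapply(seq_len(nrow(inact)), function(j)
      solve_pedestal(inact$degree_pct[j], inact$tau_ms[j], g0$tau_act), 0)
    gp <- gating_params(1, g0$v_rev, v_half, g0$k_act, g0$tau_act, inact)
    vstar <- peak_current_voltage(gp)
    gp$g_max_density <- target_mag /
      ((g0$v_rev - vstar) * boltzmann_m(vstar, v_half, g0$k_act))
    list(params = gp, capacitance_pF = cap,
         peak_density_target = -target_mag, seed = as.integer(seed))
  })
}

# pedestal fraction r of h(t) = r + (1 - r) exp(-t / tau): solved so that
# on a canonical 3 s / 1 kHz pulse the measured degree of inactivation
# (mean of the last 50 ms over the most-negative 50 ms running mean, the
# estimator used by percent_inactivation) equals degree_pct exactly
solve_pedestal <- function(degree_pct, tau_ms, tau_act,
                           duration = 3000, dt = 1, window_ms = 50) {
  target <- 1 - degree_pct / 100
  if (target >= 1) return(1)    # non-inactivating limit
  tt <- seq(0, duration, by = dt)
  m <- 1 - exp(-tt / tau_act)
  e <- exp(-tt / tau_ms)
  if (target <= 0) {            # fully inactivating limit
    e_end <- exp(-duration / tau_ms)
    return(-e_end / (1 - e_end))
  }
  w <- max(1L, round(window_ms / dt))
  kern <- rep(1 / w, w)
  endsel <- tt >= duration - window_ms
  # y(r) = m*e + r*m*(1 - e) is linear in r, and so is the running mean:
  # precompute the two filtered components once instead of per iteration
  f1 <- stats::filter(m * e, kern, sides = 2)
  f2 <- stats::filter(m * (1 - e), kern, sides = 2)
  ok <- !is.na(f1)
  f1 <- f1[ok]; f2 <- f2[ok]
  a_end <- mean((m * e)[endsel])
  b_end <- mean((m * (1 - e))[endsel])
  f <- function(r) (a_end + r * b_end) / max(f1 + r * f2) - target
  stats::uniroot(f, lower = -0.2, upper = 1, tol = 1e-12)$root
}

# inactivation-table row whose voltage is nearest to v (ties -> higher V)
nearest_inact_row <- function(inact, v) {
  d <- abs(inact$voltage_mV - v)
  cand <- which(d == min(d))
  cand[which.max(inact$voltage_mV[cand])]
}

#' Simulate one voltage-clamp sweep
#'
#' Current kinetics are
#' \eqn{I(t) = I_{ss}(V)\,(1 - e^{-t/\tau_{act}})\,(r + (1 - r) e^{-t/\tau_{inact}})},
#' with \eqn{I_{ss}} the Boltzmann-ohmic steady-state current and the
#' pedestal `r` calibrated so that the measured degree of inactivation of a
#' noiseless 3 s pulse ([percent_inactivation()]) equals the cell's
#' `degree_pct` exactly. Additive white Gaussian noise of SD `noise_sd_pA`
#' is applied when a `noise_seed` is given.
#'
#' @param cell A cell from [sample_cell()].
#' @param protocol A `vc_protocol`.
#' @param test_voltage One of `protocol$test_voltages` (mV).
#' @param noise_sd_pA Recording noise SD (pA); 0 disables noise.
#' @param noise_seed Seed for the noise draw (required when noise is on).
#' @return An object of class `sweep`: list with `test_voltage`, `time_ms`,
#'   `current_pA`, `protocol_name`.
#' @export
simulate_sweep <- function(cell, protocol, test_voltage,
                           noise_sd_pA = 0, noise_seed = NULL) {
  stopifnot(inherits(protocol, "vc_protocol"))
  if (!test_voltage %in% protocol$test_voltages)
    stop("protocol error: test voltage ", test_voltage,
         " not in protocol ", protocol$name, call. = FALSE)
  p <- cell$params
  tt <- seq(0, protocol$duration, by = 1 / protocol$sample_rate)
  i_ss <- iv_current(test_voltage, p) * cell$capacitance_pF   # pA
  m <- 1 - exp(-tt / p$tau_act)
  row <- nearest_inact_row(p$inact, test_voltage)
  r <- if ("pedestal_r" %in% names(p$inact)) p$inact$pedestal_r[row] else
    solve_pedestal(p$inact$degree_pct[row], p$inact$tau_ms[row], p$tau_act)
  h <- r + (1 - r) * exp(-tt / p$inact$tau_ms[row])
  cur <- i_ss * m * h
  if (noise_sd_pA > 0) {
    if (is.null(noise_seed))
      stop("noise_seed required when noise_sd_pA > 0", call. = FALSE)
    cur <- cur + with_local_seed(noise_seed,
                                 stats::rnorm(length(tt), 0, noise_sd_pA))
  }
  structure(list(test_voltage = test_voltage, time_ms = tt,
                 current_pA = cur, protocol_name = protocol$name),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("Sweep (%s) to %+g mV: %d samples over %g ms, peak %.1f pA\n",
              x$protocol_name, x$test_voltage, length(x$time_ms),
              max(x$time_ms), min(x$current_pA)))
  invisible(x)
}

#' Generate a full condition group of synthetic recordings
#'
#' Draws `n_cells` cells from `preset` (per-cell seeds derived
#' deterministically from `master_seed`) and simulates, for each, the full
#' I-V protocol plus both 3 s inactivation sweeps.
#'
#' @param preset A [condition_preset()].
#' @param n_cells Number of cells (default: the group size of the original
#'   experiment stored in the preset).
#' @param master_seed Integer master seed.
#' @param iv,inact Protocols (defaults: [iv_protocol()],
#'   [inactivation_protocol()]).
#' @param noise_sd_pA Noise SD; default the preset's value.
#' @return List with `recordings` (list of `cell_recording`) and `manifest`
#'   (preset name, seeds, protocol definitions).
#' @export
generate_condition_group <- function(preset, n_cells = preset$n_cells,
                                     master_seed,
                                     iv = iv_protocol(),
                                     inact = inactivation_protocol(),
                                     noise_sd_pA = preset$noise_sd_pA) {
  stopifnot(n_cells >= 1)
  seeds <- with_local_seed(master_seed,
                           sample.int(.Machine$integer.max - 1, 2 * n_cells))
  cell_seeds <- seeds[seq_len(n_cells)]
  noise_base <- seeds[n_cells + seq_len(n_cells)]
  recordings <- lapply(seq_len(n_cells), function(i) {
    cell <- sample_cell(preset, cell_seeds[i])
    ns <- 0L
    mk <- function(protocol, v) {
      ns <<- ns + 1L
      simulate_sweep(cell, protocol, v, noise_sd_pA = noise_sd_pA,
                     noise_seed = (noise_base[i] + ns) %% .Machine$integer.max)
    }
    sweeps <- c(lapply(iv$test_voltages, mk, protocol = iv),
                lapply(inact$test_voltages, mk, protocol = inact))
    structure(list(cell_id = sprintf("%s_cell%02d", preset$name, i),
                   condition = preset$name,
                   capacitance_pF = cell$capacitance_pF,
                   seed = cell_seeds[i], params = cell$params,
                   sweeps = sweeps),
              class = "cell_recording")
  })
  manifest <- list(preset = preset$name, master_seed = master_seed,
                   n_cells = n_cells, cell_seeds = cell_seeds,
                   noise_sd_pA = noise_sd_pA,
                   protocols = list(iv = unclass(iv),
                                    inact = unclass(inact)))
  list(recordings = recordings, manifest = manifest)
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf("Recording %s (%s): Cm %.1f pF, %d sweeps\n", x$cell_id,
              x$condition, x$capacitance_pF, length(x$sweeps)))
  invisible(x)
}
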