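test_that("peak detection: sign convention, ties, blanking, outward flag", {
  tt <- seq(0, 20, by = 0.05)
  expect_equal(as.numeric(detect_peak_current(
    mk_sweep(tt, rep(-100, length(tt)), protocol_name = "iv_20ms"))), -100)
  # earliest most-negative sample wins
  cur <- rep(0, length(tt)); cur[c(100, 200)] <- -50
  pk <- detect_peak_current(mk_sweep(tt, cur, protocol_name = "iv_20ms"))
  expect_equal(attr(pk, "time_ms"), tt[100])
  # blanking window hides an early artifact
  cur2 <- rep(-10, length(tt)); cur2[2] <- -1e4
  pk2 <- detect_peak_current(mk_sweep(tt, cur2, protocol_name = "iv_20ms"),
                             blank_ms = 1)
  expect_equal(as.numeric(pk2), -10)
  # outward-only trace: minimum returned, flagged
  pk3 <- detect_peak_current(mk_sweep(tt, seq(5, 50, length.out = length(tt)),
                                      protocol_name = "iv_20ms"))
  expect_true(attr(pk3, "no_inward_current"))
  expect_gt(as.numeric(pk3), 0)
  expect_error(detect_peak_current(mk_sweep(numeric(0), numeric(0))), "empty")
})

test_that("current density is peak over capacitance", {
  expect_equal(current_density(-1498, 10), -149.8)
  expect_equal(current_density(0, 12), 0)
  expect_equal(current_density(-234, 12), -19.5)
  expect_error(current_density(-100, 0), "capacitance")
})

test_that("I-V curves have one ordered point per voltage; argmin matches
           the reported peak voltages", {
  rec <- noiseless_recording(zero_var_preset("vehicle"))
  curve <- build_iv_curve(rec)
  expect_equal(nrow(curve), 23)
  expect_true(all(diff(curve$voltage_mV) > 0))
  expect_equal(curve$voltage_mV[which.min(curve$density_pA_pF)], 15)
  rec6 <- noiseless_recording(zero_var_preset("tun06"))
  curve6 <- build_iv_curve(rec6)
  expect_equal(curve6$voltage_mV[which.min(curve6$density_pA_pF)], 10)
  # stripping the iv sweeps must error
  rec$sweeps <- Filter(function(s) s$protocol_name != "iv_20ms", rec$sweeps)
  expect_error(build_iv_curve(rec), "incomplete")
})

test_that("normalization maps the peak to -1, keeps zeros, is idempotent", {
  c1 <- mk_curve(c(-50, 0, 15, 30, 60), c(0, -80, -149.8, -100, 0))
  n1 <- normalize_iv(c1)
  expect_equal(min(n1$density_pA_pF), -1)
  expect_equal(n1$density_pA_pF[c1$density_pA_pF == 0], c(0, 0))
  expect_equal(normalize_iv(n1)$density_pA_pF, n1$density_pA_pF)
  expect_error(normalize_iv(mk_curve(1:6, rep(0, 6))), "degenerate")
})

test_that("Boltzmann fit recovers noiseless model curves to 1e-4", {
  presets <- make_presets()
  v <- seq(-50, 60, 5)
  for (nm in c("vehicle", "tun06", "n283q")) {
    g <- presets[[nm]]$gating
    fit <- fit_boltzmann_iv(mk_curve(v, iv_current(v, g)))
    expect_true(fit$converged)
    expect_lt(abs(fit$v_half - g$v_half_act), 1e-4)
    expect_lt(abs(fit$k - g$k_act), 1e-4)
    expect_lt(abs(fit$v_rev - g$v_rev), 1e-4)
    expect_lt(abs(fit$g_max - g$g_max_density) / g$g_max_density, 1e-4)
  }
})

test_that("fit is scale-invariant in shape parameters; normalized and raw
           curves agree", {
  g <- make_presets()$vehicle$gating
  v <- seq(-50, 60, 5)
  raw <- mk_curve(v, iv_current(v, g))
  f1 <- fit_boltzmann_iv(raw)
  f2 <- fit_boltzmann_iv(mk_curve(v, 3.7 * raw$density_pA_pF))
  f3 <- fit_boltzmann_iv(normalize_iv(raw))
  for (f in list(f2, f3)) {
    expect_equal(f$v_half, f1$v_half, tolerance = 1e-6)
    expect_equal(f$k, f1$k, tolerance = 1e-6)
    expect_equal(f$v_rev, f1$v_rev, tolerance = 1e-6)
  }
  expect_equal(f2$g_max / f1$g_max, 3.7, tolerance = 1e-6)
})

test_that("optimizer matches the brute-force lattice oracle on noisy
           curves", {
  g <- make_presets()$vehicle$gating
  v <- seq(-50, 60, 5)
  set.seed(99)
  for (i in 1:5) {
    y <- iv_current(v, g) + stats::rnorm(length(v), 0, 4)
    curve <- mk_curve(v, y)
    fit <- fit_boltzmann_iv(curve)
    oracle <- boltzmann_grid_oracle(curve)
    expect_lte(fit$rss, oracle$rss * 1.01)
  }
})

test_that("degenerate and malformed curves are rejected", {
  expect_error(fit_boltzmann_iv(mk_curve(seq(-50, 60, 5), rep(0, 23))),
               "degenerate")
  expect_error(fit_boltzmann_iv(mk_curve(c(-10, 0, 10, 20),
                                         c(-1, -2, -3, -4))), "6 points")
})

test_that("v_half_shift averages converged fits and flags exclusions", {
  g <- make_presets()$vehicle$gating
  v <- seq(-50, 60, 5)
  fit <- fit_boltzmann_iv(mk_curve(v, iv_current(v, g)))
  expect_equal(v_half_shift(list(fit, fit), list(fit, fit))$shift_mV, 0)
  bad <- fit; bad$converged <- FALSE
  res <- v_half_shift(list(fit, bad), list(fit))
  expect_equal(res$group_a$excluded, 1)
  expect_error(v_half_shift(list(bad), list(fit)), "no converged")
})

test_that("v_half recovery bias over 200 noisy vehicle cells is < 0.3 mV", {
  p <- make_presets()$vehicle
  g <- generate_condition_group(p, 200, master_seed = 271)
  a <- analyze_iv_group(g$recordings)
  expect_lt(abs(mean(a$v_half) - p$gating$v_half_act), 0.3)
})
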