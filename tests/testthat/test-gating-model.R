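test_that("steady-state activation follows the Boltzmann closed form", {
  p <- make_presets()$vehicle$gating
  expect_equal(steady_state_activation(p$v_half_act, p), 0.5)
  expect_equal(steady_state_activation(p$v_half_act + p$k_act, p),
               1 / (1 + exp(-1)))
  # frozen closed-form value at the solved vehicle midpoint
  g <- gating_params(1, 60, 5.11, 4.5)
  expect_equal(steady_state_activation(15, g), 0.90005, tolerance = 1e-4)
  expect_error(steady_state_activation(NaN, p), "finite")
  expect_error(steady_state_activation(Inf, p), "finite")
})

test_that("activation is strictly increasing and saturates at 0/1", {
  p <- make_presets()$tun06$gating
  v <- seq(-120, 120, by = 0.5)
  m <- steady_state_activation(v, p)
  expect_true(all(diff(m) > 0))
  expect_lt(steady_state_activation(-500, p), 1e-10)
  expect_gt(steady_state_activation(500, p), 1 - 1e-10)
})

test_that("iv_current vanishes at v_rev, is inward below, linear in g_max", {
  presets <- make_presets()
  for (p in presets) {
    g <- p$gating
    expect_identical(iv_current(g$v_rev, g), 0)
    expect_true(all(iv_current(seq(-50, g$v_rev - 1, 5), g) < 0))
    g2 <- g
    g2$g_max_density <- 2 * g$g_max_density
    v <- seq(-50, 60, 5)
    expect_equal(iv_current(v, g2), 2 * iv_current(v, g))
  }
})

test_that("peak voltage from grid search matches the closed-form relation", {
  presets <- make_presets()
  v <- seq(-50, 59.99, by = 0.01)
  for (p in presets) {
    g <- p$gating
    v_grid <- v[which.max(abs(iv_current(v, g)))]
    v_closed <- peak_current_voltage(g)
    expect_lt(abs(v_grid - v_closed), 0.02)
    # stationarity identity (v_rev - v*)(1 - m(v*)) = k
    m <- steady_state_activation(v_closed, g)
    expect_equal((g$v_rev - v_closed) * (1 - m), g$k_act, tolerance = 1e-8)
  }
})

test_that("vehicle midpoint is solved from the +15 mV peak constraint", {
  expect_equal(solve_v_half_for_peak(15, 4.5, 60), 15 - 4.5 * log(9))
  expect_equal(solve_v_half_for_peak(15, 4.5, 60), 5.1125, tolerance = 1e-4)
  p <- make_presets()
  expect_equal(peak_current_voltage(p$vehicle$gating), 15, tolerance = 1e-8)
  expect_error(solve_v_half_for_peak(59.9, 4.5, 60), "interior")
})

test_that("presets encode the reported group means and shifts", {
  p <- make_presets()
  expect_named(p, c("vehicle", "tun02", "tun06", "tun20", "no_a2d1",
                    "wt_exp2", "n283q", "n283q_vehicle", "n283q_tun06"))
  expect_equal(p$vehicle$mean_peak_density, -149.8)
  expect_equal(p$tun06$mean_peak_density, -26.7)
  expect_equal(p$n283q$mean_peak_density, -19.5)
  expect_equal(p$vehicle$n_cells, 27L)
  expect_equal(p$tun06$gating$v_half_act - p$vehicle$gating$v_half_act, -5)
  expect_equal(p$tun02$gating$v_half_act - p$vehicle$gating$v_half_act, -3.5)
  expect_equal(p$n283q_tun06$gating$v_half_act -
                 p$n283q_vehicle$gating$v_half_act, -4.5)
  # N283Q leaves activation untouched
  expect_equal(p$n283q$gating$v_half_act, p$vehicle$gating$v_half_act)
  # inactivation-degree differences (percentage points) vs controls
  d <- function(x, v) x$gating$inact$degree_pct[x$gating$inact$voltage_mV == v]
  expect_equal(d(p$vehicle, 20) - d(p$tun06, 20), 14)
  expect_equal(d(p$vehicle, 0) - d(p$tun06, 0), 16)
  expect_equal(d(p$wt_exp2, 20) - d(p$n283q, 20), 22)
  expect_equal(d(p$wt_exp2, 0) - d(p$n283q, 0), 35)
  # between-cell SD reconstructed as SEM * sqrt(n)
  expect_equal(p$vehicle$variability$peak_density_cv,
               14.9 * sqrt(27) / 149.8)
})

test_that("preset overrides are applied and invariants enforced", {
  p <- make_presets(list(vehicle = list(noise_sd_pA = 2,
                                        gating = list(k_act = 6))))
  expect_equal(p$vehicle$noise_sd_pA, 2)
  expect_equal(p$vehicle$gating$k_act, 6)
  expect_error(make_presets(list(vehicle = list(gating = list(k_act = -1)))),
               "configuration error")
  expect_error(make_presets(list(bogus = list(noise_sd_pA = 1))),
               "configuration error")
  expect_error(make_presets(list(vehicle = list(mean_peak_density = 10))),
               "configuration error")
})

test_that("presets round-trip through the config file bit-identically", {
  p <- make_presets()
  f <- withr::local_tempfile(fileext = ".cfg")
  write_presets_config(p, f)
  p2 <- read_presets_config(f)
  expect_identical(names(p2), names(p))
  for (nm in names(p)) {
    a <- unclass(p[[nm]]); b <- unclass(p2[[nm]])
    expect_identical(a$n_cells, as.integer(b$n_cells))
    expect_identical(a$mean_peak_density, b$mean_peak_density)
    expect_identical(unclass(a$gating)[c("g_max_density", "v_rev",
                                         "v_half_act", "k_act", "tau_act")],
                     unclass(b$gating)[c("g_max_density", "v_rev",
                                         "v_half_act", "k_act", "tau_act")])
    expect_identical(a$gating$inact$degree_pct, b$gating$inact$degree_pct)
    expect_identical(a$gating$inact$tau_ms, b$gating$inact$tau_ms)
    expect_identical(a$variability, b$variability)
  }
})
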