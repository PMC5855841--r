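# independent brute-force oracles, kept free of the package's fitting code

# exhaustive lattice search for the Boltzmann-ohmic fit: v_half and k on a
# fixed grid, g_max and v_rev by linear least squares per lattice point
# (I = g*(V - Vr)*m = a*(V*m) + b*m with a = g, b = -g*Vr)
boltzmann_grid_oracle <- function(curve, v_half_range = c(-10, 15),
                                  k_range = c(2, 8), step = 0.05) {
  v <- curve$voltage_mV
  y <- curve$density_pA_pF
  best <- list(rss = Inf)
  for (vh in seq(v_half_range[1], v_half_range[2], by = step)) {
    for (k in seq(k_range[1], k_range[2], by = step)) {
      m <- 1 / (1 + exp(-(v - vh) / k))
      X <- cbind(v * m, m)
      cf <- stats::lm.fit(X, y)$coefficients
      rss <- sum((y - X %*% cf)^2)
      if (rss < best$rss)
        best <- list(rss = rss, v_half = vh, k = k, g_max = cf[[1]],
                     v_rev = -cf[[2]] / cf[[1]])
    }
  }
  best
}

# dense log-grid search for the single-exponential decay time constant,
# with amplitude and pedestal by linear least squares per grid point
tau_grid_oracle <- function(tt, y, n_grid = 2000) {
  taus <- exp(seq(log(1), log(10 * (max(tt) - tt[1])), length.out = n_grid))
  rss <- vapply(taus, function(tau) {
    x <- exp(-(tt - tt[1]) / tau)
    sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  }, 0)
  list(tau = taus[which.min(rss)], rss = min(rss))
}
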