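# shared builders: deterministic cells/recordings for analysis tests

zero_var_preset <- function(name = "vehicle") {
  p <- make_presets()[[name]]
  p$variability[] <- lapply(p$variability, function(x) 0)
  p$noise_sd_pA <- 0
  p
}

# noiseless recording for one cell sampled from `preset`
noiseless_recording <- function(preset, seed = 1,
                                voltages = seq(-50, 60, 5)) {
  cell <- sample_cell(preset, seed)
  iv <- iv_protocol(voltages)
  ip <- inactivation_protocol()
  sweeps <- c(lapply(voltages, function(v)
                simulate_sweep(cell, iv, v, noise_sd_pA = 0)),
              lapply(ip$test_voltages, function(v)
                simulate_sweep(cell, ip, v, noise_sd_pA = 0)))
  structure(list(cell_id = paste0(preset$name, "_test"),
                 condition = preset$name,
                 capacitance_pF = cell$capacitance_pF, seed = seed,
                 params = cell$params, sweeps = sweeps),
            class = "cell_recording")
}

mk_curve <- function(voltage, density, cell_id = "c") {
  cavgate:::new_iv_curve(voltage, density, normalized = FALSE,
                         cell_id = cell_id)
}

mk_sweep <- function(time_ms, current_pA, test_voltage = 0,
                     protocol_name = "inact_3s") {
  structure(list(test_voltage = test_voltage, time_ms = time_ms,
                 current_pA = current_pA, protocol_name = protocol_name),
            class = "sweep")
}
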