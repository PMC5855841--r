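# One-call in-silico replication of the gating experiments: simulate every
# condition group at its original size and recover the group-level effects
# through the full analysis pipeline.

#' Replicate the gating study on synthetic recordings
#'
#' Simulates the five condition groups involved in the headline gating
#' effects at their original group sizes (vehicle n = 27, tunicamycin 0.2
#' n = 13, tunicamycin 0.6 n = 16, wild type n = 13, N283Q n = 19) with
#' default recording noise, then runs the complete analysis pipeline
#' (peak detection, density normalization, Boltzmann I-V fits, 3 s
#' inactivation quantification) and reports the recovered group effects.
#'
#' @param seed Integer seed; the per-group master seeds are derived from it
#'   deterministically.
#' @param presets Preset list, defaults to [make_presets()].
#' @return List with elements:
#'   `vhalf_shift_tun06_mV`, `vhalf_shift_tun02_mV` (mean vehicle V1/2
#'   minus mean treated V1/2, mV);
#'   `degree_diff_tun06_0mV`, `degree_diff_n283q_0mV` (difference in
#'   group-mean degree of inactivation at 0 mV, percentage points);
#'   `vehicle_mean_density_pA_pF` (group-mean peak current density);
#'   `n_cells` (named group sizes); `tables` (per-cell analysis tables).
#' @export
run_study <- function(seed, presets = make_presets()) {
  seeds <- with_local_seed(seed, sample.int(2^31 - 2, 5))
  groups <- list(
    vehicle = generate_condition_group(presets$vehicle, master_seed = seeds[1]),
    tun02   = generate_condition_group(presets$tun02, master_seed = seeds[2]),
    tun06   = generate_condition_group(presets$tun06, master_seed = seeds[3]),
    wt_exp2 = generate_condition_group(presets$wt_exp2, master_seed = seeds[4]),
    n283q   = generate_condition_group(presets$n283q, master_seed = seeds[5]))
  ivs <- lapply(groups, function(g) analyze_iv_group(g$recordings))
  inact0 <- lapply(groups, function(g)
    analyze_inactivation_group(g$recordings, 0))
  mean_vh <- function(tab) mean(tab$v_half[tab$converged])
  list(
    vhalf_shift_tun06_mV = mean_vh(ivs$vehicle) - mean_vh(ivs$tun06),
    vhalf_shift_tun02_mV = mean_vh(ivs$vehicle) - mean_vh(ivs$tun02),
    degree_diff_tun06_0mV = mean(inact0$vehicle$degree_pct, na.rm = TRUE) -
      mean(inact0$tun06$degree_pct, na.rm = TRUE),
    degree_diff_n283q_0mV = mean(inact0$wt_exp2$degree_pct, na.rm = TRUE) -
      mean(inact0$n283q$degree_pct, na.rm = TRUE),
    vehicle_mean_density_pA_pF = mean(ivs$vehicle$peak_density_pA_pF),
    n_cells = vapply(groups, function(g) g$manifest$n_cells, 0L),
    tables = list(iv = ivs, inactivation_0mV = inact0))
}
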