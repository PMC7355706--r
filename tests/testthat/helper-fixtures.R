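# Shared fixtures: everything is generated in code, no stored data.

ref_claritin_metrics <- function() {
  tibble::tibble(cmax_ug_per_ml = 0.0019, auc_ug_min_per_ml = 0.30)
}

# a scenario with no residual floor, for closed-form volume checks
no_floor_condition <- function(t_half = 15, k_sec_s = 1, k_sec_d = 1) {
  condition_config("no-floor test", gastric_residual_floor = 0,
                   k_sec_s = k_sec_s, k_sec_d = k_sec_d,
                   t_half_gastric = t_half, duration = 60)
}

zero_kinetics_params <- function() {
  transit_parameters(z_s = 0, z_d = 0, z_j = 0, frac = 0,
                     k_pre_d = 0, k_pre_j = 0)
}

# initial guess for recovery fits: free parameters at the mid-bound default,
# fixed parameters pinned to the generating truth
recovery_guess <- function(truth, free) {
  b <- default_transit_bounds()
  val <- function(nm) {
    if (!nm %in% free) return(truth[[nm]])
    if (nm == "frac") 0.5 else sqrt(b[[nm]][1] * b[[nm]][2])
  }
  transit_parameters(z_s = val("z_s"), z_d = val("z_d"), z_j = val("z_j"),
                     frac = val("frac"), k_pre_d = val("k_pre_d"),
                     k_pre_j = val("k_pre_j"),
                     z_unit_scale = truth$z_unit_scale)
}

wide_volumes <- function(traj) {
  tidyr::pivot_wider(
    tibble::as_tibble(traj)[, c("time_min", "compartment", "volume_ml")],
    names_from = "compartment", values_from = "volume_ml")
}
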