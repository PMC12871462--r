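# Shared fixtures: small, fast configurations used across test files.
# All simulated fixtures are generated in code; nothing is read from disk.

# Noiseless single-replicate SIP design, shortened to three replenishment
# cycles (no swap) - enough for budget closure without the full 30 days.
quiet_sip_config <- function(targets = c(10, 100), ...) {
  incubation_config(target_ch4 = targets, replicates = 1,
                    duration = 216, replenish_interval = 72,
                    sampling_interval = 12, headspace_swap_time = NA_real_,
                    include_sterile_control = FALSE,
                    include_ambient_control = FALSE,
                    measurement_cv = 0, delta_sd = 0, seed = 42L, ...)
}

# Noiseless short rate assay across the full concentration range.
quiet_rate_config <- function(...) {
  rate_assay_config(sampling_interval = 0.5, replicates = 1,
                    measurement_cv = 0, delta_sd = 0, seed = 42L, ...)
}

# Closed-form Michaelis-Menten rates on the standard concentration ladder.
mm_rates <- function(vmax, km, s = c(2, 10, 50, 100, 250, 500)) {
  data.frame(concentration = s, rate = vmax * s / (km + s))
}
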