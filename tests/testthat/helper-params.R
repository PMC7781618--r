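# Shared fixture builders. All fixtures are constructed in code.

# Representative short-variant channel: activation/inactivation parameters of
# the 8b-43S reference construct, mid-QC-window amplitude.
demo_params <- function(g_leak = 1, noise_sd = 5, c_m = 20,
                        tau_act = 0.5, tau_fast = 80, tau_slow = 1000,
                        tau_cap = 0.2, plateau = 0.1784) {
  channel_params(
    activation_params(v_half = -10.21, slope = 8.51, g_max = 8,
                      v_rev = 65.70, tau_act = tau_act),
    inactivation_params(v_half = -35.71, slope = 5.52, plateau = plateau,
                        tau_fast = tau_fast, tau_slow = tau_slow),
    passive_params(g_leak = g_leak, noise_sd = noise_sd, c_m = c_m,
                   tau_cap = tau_cap)
  )
}

# Quasi-steady-state configuration: activation fast relative to the step,
# inactivation and capacitive transient effectively off, no leak or noise.
# In this limit simulated peak currents equal the closed-form I-V equation
# to machine precision, which is the oracle the fitting tests rely on.
oracle_params <- function(v_half = -13.40, slope = 7.60, g_max = 8,
                          v_rev = 64.75) {
  channel_params(
    activation_params(v_half, slope, g_max, v_rev, tau_act = 0.05),
    inactivation_params(-39.94, 4.94, plateau = 0.1082,
                        tau_fast = 1e7, tau_slow = 1e7),
    passive_params(g_leak = 0, noise_sd = 0, tau_cap = 0.02)
  )
}

# Analytic peak table from the I-V equation itself (no simulation).
analytic_peaks <- function(v, v_half, slope, g_max, v_rev, c_m = 20) {
  i <- g_max * (v - v_rev) / (1 + exp(-(v - v_half) / slope))
  out <- data.frame(test_v = v, peak_pa = i, norm_pa_pf = i / c_m)
  class(out) <- c("peak_table", "data.frame")
  attr(out, "c_m") <- c_m
  out
}
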