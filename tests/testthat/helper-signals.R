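# Shared fixtures: small signals and traces built in code.

test_config <- function() radar_config()

# A bare trace with linear displacement (constant radial velocity).
linear_trace <- function(v0, n = 4096, prf = 2000) {
  structure(list(time_s = (0:(n - 1)) / prf,
                 displacement_m = v0 * (0:(n - 1)) / prf,
                 velocity_m_s = rep(v0, n),
                 per_cycle_truth = NULL, prf_hz = prf, aspect_angle_deg = 0),
            class = "kinematics_trace")
}

# Complex tone as a slow_time_signal.
tone_signal <- function(f0, n = 1024, prf = 2000, lam = radar_config()$wavelength_m) {
  structure(list(samples = exp(1i * 2 * pi * f0 * (0:(n - 1)) / prf),
                 prf_hz = prf, wavelength_m = lam, provenance = list()),
            class = "slow_time_signal")
}
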