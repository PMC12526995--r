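#' FMCW radar configuration
#'
#' Bundles the parameters of a frequency-modulated continuous-wave radar and
#' derives the quantities the rest of the toolkit needs: wavelength, slow-time
#' sampling rate (PRF), chirp frequency slope and range resolution. Defaults
#' follow a 77 GHz automotive-band sensor with 3.99 GHz sweep bandwidth and a
#' 0.5 ms frame period.
#'
#' @param carrier_frequency_hz Carrier frequency \eqn{f_c} in Hz.
#' @param bandwidth_hz Sweep bandwidth \eqn{B} in Hz.
#' @param chirp_duration_s Duration \eqn{T} of one chirp in seconds. The
#'   frequency slope is \eqn{S_w = B/T}.
#' @param slow_time_interval_s Frame period in seconds; its reciprocal is the
#'   slow-time sampling rate (PRF) that bounds unambiguous Doppler to
#'   \eqn{\pm PRF/2}.
#' @param samples_per_chirp Fast-time samples recorded per chirp.
#' @param chirps_per_frame Number of chirps per frame (phase extraction uses
#'   chirp 0 only).
#' @param n_frames Number of frames in a capture.
#' @param tx_amplitude,rx_amplitude Transmit/receive amplitudes used by the
#'   chirp-level simulator.
#'
#' @return An object of class `radar_config`: a list with the fields above
#'   plus `wavelength_m`, `prf_hz`, `slope_hz_per_s` and `range_resolution_m`.
#' @examples
#' cfg <- radar_config()
#' cfg$wavelength_m * 1e3   # ~3.893 mm
#' cfg$prf_hz               # 2000 Hz
#' @export
radar_config <- function(carrier_frequency_hz = 77e9,
                         bandwidth_hz = 3.99e9,
                         chirp_duration_s = 50e-6,
                         slow_time_interval_s = 0.5e-3,
                         samples_per_chirp = 128L,
                         chirps_per_frame = 3L,
                         n_frames = 50000L,
                         tx_amplitude = 1,
                         rx_amplitude = 1) {
  stopifnot_scalar(carrier_frequency_hz, "carrier_frequency_hz")
  stopifnot_scalar(bandwidth_hz, "bandwidth_hz")
  stopifnot_scalar(chirp_duration_s, "chirp_duration_s")
  stopifnot_scalar(slow_time_interval_s, "slow_time_interval_s")
  cfg <- list(
    carrier_frequency_hz = carrier_frequency_hz,
    bandwidth_hz = bandwidth_hz,
    chirp_duration_s = chirp_duration_s,
    slow_time_interval_s = slow_time_interval_s,
    samples_per_chirp = as.integer(samples_per_chirp),
    chirps_per_frame = as.integer(chirps_per_frame),
    n_frames = as.integer(n_frames),
    tx_amplitude = tx_amplitude,
    rx_amplitude = rx_amplitude,
    wavelength_m = .c0 / carrier_frequency_hz,
    prf_hz = 1 / slow_time_interval_s,
    slope_hz_per_s = bandwidth_hz / chirp_duration_s,
    range_resolution_m = .c0 / (2 * bandwidth_hz)
  )
  class(cfg) <- "radar_config"
  cfg
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  carrier      %.2f GHz  (wavelength %.4f mm)\n",
              x$carrier_frequency_hz / 1e9, x$wavelength_m * 1e3))
  cat(sprintf("  bandwidth    %.3f GHz  (range resolution %.2f cm)\n",
              x$bandwidth_hz / 1e9, x$range_resolution_m * 1e2))
  cat(sprintf("  frame period %.3f ms   (PRF %.0f Hz)\n",
              x$slow_time_interval_s * 1e3, x$prf_hz))
  cat(sprintf("  chirp %.1f us, slope %.2f MHz/us, %d samples x %d chirps x %d frames\n",
              x$chirp_duration_s * 1e6, x$slope_hz_per_s / 1e12,
              x$samples_per_chirp, x$chirps_per_frame, x$n_frames))
  invisible(x)
}
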