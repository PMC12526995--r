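#' Time-frequency map container
#'
#' All three representations (STFT spectrogram, Wigner-Ville distribution,
#' smoothed pseudo-WVD) return a `tf_map`: a real matrix `power`
#' (frequency x time, linear scale; WVD values may be negative), a signed
#' frequency axis centered on zero (negative = toward the radar), a strictly
#' increasing time axis and method/window metadata.
#'
#' @name tf_map
NULL

new_tf_map <- function(power, freq_axis_hz, time_axis_s, method, window = list(),
                       prf_hz = NULL) {
  stopifnot(nrow(power) == length(freq_axis_hz),
            ncol(power) == length(time_axis_s),
            all(diff(time_axis_s) > 0))
  structure(list(power = power, freq_axis_hz = freq_axis_hz,
                 time_axis_s = time_axis_s, method = method,
                 window = window, prf_hz = prf_hz),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map %s>  %d freq bins x %d time bins, f in [%.1f, %.1f] Hz, t in [%.3f, %.3f] s\n",
              x$method, nrow(x$power), ncol(x$power),
              min(x$freq_axis_hz), max(x$freq_axis_hz),
              min(x$time_axis_s), max(x$time_axis_s)))
  invisible(x)
}

as_complex_samples <- function(signal) {
  if (inherits(signal, "slow_time_signal")) signal$samples else as.complex(signal)
}

signal_prf <- function(signal, prf_hz) {
  if (inherits(signal, "slow_time_signal")) signal$prf_hz
  else if (!is.null(prf_hz)) prf_hz
  else stop("supply `prf_hz` for plain numeric signals", call. = FALSE)
}

#' STFT spectrogram of a slow-time signal
#'
#' Squared-magnitude short-time Fourier transform with a Hamming window. The
#' two-sided (signed-Doppler) spectrum is returned with zero frequency in the
#' middle. Frequency resolution is `PRF / window_length` and time resolution
#' `window_length / PRF`: a 64-point window at PRF 2000 Hz gives 31.25 Hz and
#' 32 ms, a 256-point window 7.81 Hz and 128 ms — the classic window
#' trade-off of linear time-frequency analysis.
#'
#' @param signal A `slow_time_signal`, or a complex vector (then give
#'   `prf_hz`).
#' @param window_length Analysis window length in samples.
#' @param overlap Overlap between consecutive windows in samples
#'   (default 75%).
#' @param fft_length Zero-padded FFT length, `>= window_length`.
#' @param prf_hz Sampling rate for plain vectors.
#' @return A [tf_map] with `method = "STFT"`; power is nonnegative.
#' @examples
#' cfg <- radar_config()
#' tr <- simulate_kinematics(compression_scenario(5, 100, duration_s = 3), cfg)
#' S <- stft_spectrogram(phase_synthesize(tr, cfg))
#' S$window$freq_resolution_hz  # 31.25 Hz for the default 64-point window
#' @export
stft_spectrogram <- function(signal, window_length = 64L,
                             overlap = floor(window_length * 0.75),
                             fft_length = max(256L, window_length),
                             prf_hz = NULL) {
  x <- as_complex_samples(signal)
  fs <- signal_prf(signal, prf_hz)
  window_length <- as.integer(window_length)
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  if (window_length > length(x))
    stop("window longer than the signal", call. = FALSE)
  if (overlap < 0 || overlap >= window_length)
    stop("`overlap` must lie in [0, window_length)", call. = FALSE)
  hop <- window_length - as.integer(overlap)
  nfft <- as.integer(fft_length)
  if (nfft < window_length) stop("fft_length < window_length", call. = FALSE)

  w <- signal::hamming(window_length)
  starts <- seq(1L, length(x) - window_length + 1L, by = hop)
  P <- vapply(starts, function(s) {
    seg <- x[s:(s + window_length - 1L)] * w
    Mod(stats::fft(c(seg, rep(0, nfft - window_length))))^2
  }, numeric(nfft))
  P <- fft_shift_rows(matrix(P, nrow = nfft))
  new_tf_map(P,
             freq_axis_hz = shifted_freq_axis(nfft, fs),
             time_axis_s = (starts - 1L + window_length / 2) / fs,
             method = "STFT",
             window = list(type = "hamming", length = window_length,
                           overlap = as.integer(overlap), fft_length = nfft,
                           freq_resolution_hz = fs / window_length,
                           time_resolution_s = window_length / fs),
             prf_hz = fs)
}

# Exact band-limited 2x interpolation via zero-padding the spectrum.
# The WVD lag grid advances in steps of two samples; interpolating first
# doubles the usable Doppler span to +/- PRF/2 (the convention used by
# mainstream implementations).
upsample2 <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- n %/% 2
  Xu <- complex(2 * n)
  Xu[1:h] <- X[1:h]
  Xu[(2 * n - (n - h) + 1):(2 * n)] <- X[(h + 1):n]
  stats::fft(Xu, inverse = TRUE) / n
}

#' Wigner-Ville distribution
#'
#' Bilinear time-frequency representation
#' \deqn{W(t,f) = \int x(t+\tau/2)\, x^*(t-\tau/2)\, e^{-j2\pi f\tau}\, d\tau,}
#' computed from the discrete lag product after exact 2x band-limited
#' interpolation of the signal (so the frequency axis spans the full
#' \eqn{\pm PRF/2} without lag-grid aliasing). The WVD is real but not
#' nonnegative; it localizes a linear FM chirp exactly on its instantaneous
#' frequency, at the price of oscillating cross-terms midway between any two
#' signal components. Values are scaled so that the time marginal holds:
#' \eqn{\sum_f W(t_n, f)\,\Delta f = |x(t_n)|^2}.
#'
#' Real-valued input is converted to its analytic signal first.
#'
#' @param signal A `slow_time_signal` or complex/numeric vector.
#' @param fft_length FFT length over lag; also the number of frequency bins.
#' @param hop Column spacing in (original) samples.
#' @param prf_hz Sampling rate for plain vectors.
#' @return A [tf_map] with `method = "WVD"`.
#' @export
wvd <- function(signal, fft_length = 512L, hop = 1L, prf_hz = NULL) {
  x <- as_complex_samples(signal)
  fs <- signal_prf(signal, prf_hz)
  if (length(x) < 4) stop("signal too short", call. = FALSE)
  if (is.numeric(signal) && all(Im(x) == 0)) x <- analytic_signal(Re(x))
  res <- wvd_core(x, fs, as.integer(fft_length), as.integer(hop),
                  lag_window = NULL, time_window = NULL)
  new_tf_map(res$W, res$f, res$t, "WVD",
             window = list(fft_length = as.integer(fft_length)), prf_hz = fs)
}

#' Smoothed pseudo Wigner-Ville distribution
#'
#' The WVD of [wvd()] with independent Hamming smoothing in time and in lag
#' (frequency). Smoothing suppresses the oscillatory cross-terms of the
#' bilinear distribution while keeping most of its localization: a
#' stationary ridge is unchanged, and the cross-term energy between two
#' tones drops by more than an order of magnitude. Default 256-point windows
#' (odd-adjusted internally) for both directions.
#'
#' @inheritParams wvd
#' @param time_window_length,freq_window_length Hamming window lengths in
#'   samples for time and lag smoothing; even values are reduced to the next
#'   odd number.
#' @return A [tf_map] with `method = "SPWVD"`.
#' @export
spwvd <- function(signal, time_window_length = 256L, freq_window_length = 256L,
                  fft_length = 512L, hop = 1L, prf_hz = NULL) {
  x <- as_complex_samples(signal)
  fs <- signal_prf(signal, prf_hz)
  if (length(x) < 4) stop("signal too short", call. = FALSE)
  if (is.numeric(signal) && all(Im(x) == 0)) x <- analytic_signal(Re(x))
  oddify <- function(L) { L <- as.integer(L); if (L %% 2L == 0L) L - 1L else L }
  tw <- oddify(time_window_length)
  fw <- oddify(freq_window_length)
  if (tw > 2 * length(x) || fw > 2 * length(x))
    stop("smoothing windows longer than the signal", call. = FALSE)
  g <- signal::hamming(tw); g <- g / sum(g)
  h <- signal::hamming(fw); h <- h / max(h)
  res <- wvd_core(x, fs, as.integer(fft_length), as.integer(hop),
                  lag_window = h, time_window = g)
  new_tf_map(res$W, res$f, res$t, "SPWVD",
             window = list(type = "hamming", time_length = tw,
                           freq_length = fw,
                           fft_length = as.integer(fft_length)), prf_hz = fs)
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  hgain <- numeric(n)
  if (n %% 2 == 0) {
    hgain[c(1, n / 2 + 1)] <- 1
    hgain[2:(n / 2)] <- 2
  } else {
    hgain[1] <- 1
    hgain[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * hgain, inverse = TRUE) / n
}

# Shared WVD/SPWVD kernel. Works on the 2x-interpolated signal; lag index m
# corresponds to time lag tau = m / fs, so FFT bins are k * fs / nfft.
wvd_core <- function(x, fs, nfft, hop, lag_window = NULL, time_window = NULL) {
  xu <- upsample2(x)
  nu <- length(xu)
  cols <- seq(1L, nu, by = 2L * hop)          # original sample instants
  half <- min(nfft %/% 2 - 1L, (nu - 1L) %/% 2)
  lags <- 0:half

  if (!is.null(lag_window)) {
    lw_center <- (length(lag_window) + 1L) %/% 2
    half <- min(half, lw_center - 1L)
    lags <- 0:half
  }

  K <- matrix(0i, nrow = nfft, ncol = length(cols))
  for (mi in seq_along(lags)) {
    m <- lags[mi]
    # full lag-product series over upsampled time, zero outside support
    idx_p <- seq_len(nu) + m
    idx_m <- seq_len(nu) - m
    ok <- idx_p <= nu & idx_m >= 1L
    prod_full <- complex(nu)
    prod_full[ok] <- xu[idx_p[ok]] * Conj(xu[idx_m[ok]])
    if (!is.null(time_window)) {
      sm <- stats::filter(Re(prod_full), time_window, sides = 2) +
        1i * stats::filter(Im(prod_full), time_window, sides = 2)
      sm[is.na(sm)] <- 0i
      prod_full <- as.complex(sm)
    }
    vals <- prod_full[cols]
    wgt <- if (is.null(lag_window)) 1 else lag_window[lw_center + m]
    if (m == 0L) {
      K[1L, ] <- vals * wgt
    } else {
      K[m + 1L, ] <- vals * wgt
      K[nfft - m + 1L, ] <- Conj(vals) * wgt
    }
  }
  W <- Re(stats::mvfft(K)) / fs
  list(W = fft_shift_rows(W),
       f = shifted_freq_axis(nfft, fs),
       t = (cols - 1L) / (2 * fs))
}

#' Convert a time-frequency map to a normalized grayscale image
#'
#' dB-scales the map relative to its peak, clips at `dynamic_range_db` below
#' the peak, min-max normalizes to `[0, 1]` and resizes to `out_size`
#' (bilinear). This is the preparation step for the spectrogram-image CNN.
#'
#' @param tfmap A [tf_map].
#' @param dynamic_range_db Clip level below the map's peak, in dB.
#' @param out_size Integer vector `c(height, width)` of the output image.
#' @return A numeric `out_size` matrix in `[0, 1]`.
#' @export
tf_to_image <- function(tfmap, dynamic_range_db = 60, out_size = c(64L, 64L)) {
  stopifnot(inherits(tfmap, "tf_map"))
  P <- pmax(tfmap$power, 0)
  pk <- max(P)
  if (pk <= 0) stop("degenerate all-zero map", call. = FALSE)
  db <- 10 * log10(pmax(P / pk, 10^(-dynamic_range_db / 10)))
  img <- (db + dynamic_range_db) / dynamic_range_db
  out <- EBImage::resize(img, w = out_size[1], h = out_size[2])
  out <- matrix(as.numeric(out), out_size[1], out_size[2])
  # keep the normalization contract exact after interpolation
  out <- out - min(out)
  if (max(out) > 0) out <- out / max(out)
  out
}
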