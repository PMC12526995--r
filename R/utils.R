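# Internal helpers shared across modules.

# Speed of light [m/s].
.c0 <- 2.99792458e8

#' @noRd
stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# Indices of local minima of a numeric vector. Plateaus count once, at their
# first index; endpoints are never minima.
#' @noRd
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  # carry the last nonzero slope forward so flat runs inherit the approach
  # direction
  idx <- cumsum(nz)
  filled <- s
  filled[idx > 0] <- s[nz][idx[idx > 0]]
  turns <- which(filled[-1] == 1 & filled[-length(filled)] == -1) + 1L
  vapply(turns, function(i) {
    while (i > 1L && x[i - 1L] == x[i]) i <- i - 1L
    as.integer(i)
  }, integer(1))
}

# Centered moving average; width clipped to an odd number of taps >= 1.
#' @noRd
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  y <- as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
  y[is.na(y)] <- x[is.na(y)]
  y
}

# Round half away from zero (the convention used when comparing against
# 3-decimal printed table entries; IEEE round-half-even would flip several
# cells ending in 5).
#' @export
#' @rdname reproduce_printed_tables
round_half_away <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# fftshift for a vector or the rows of a matrix (frequency axis first).
#' @noRd
fft_shift_rows <- function(M) {
  n <- nrow(M)
  M[c((n %/% 2 + 1):n, 1:(n %/% 2)), , drop = FALSE]
}

#' @noRd
shifted_freq_axis <- function(nfft, fs) {
  ((-(nfft %/% 2)):(nfft %/% 2 - 1)) * fs / nfft
}

# Deterministic child seeds derived from one master seed.
#' @noRd
fan_out_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% .Machine$integer.max
}

#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
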