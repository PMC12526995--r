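#' Fit a polynomial regression of depth on peak Doppler frequency
#'
#' Least-squares polynomial fit of reference compression depth (cm) on the
#' per-cycle maximum Doppler frequency (Hz). The minimizer of the mean
#' squared error solves the normal equations
#' \eqn{X^\top X w = X^\top y}; for numerical stability the solution is
#' computed by QR least squares on a z-scored feature (identical to the
#' closed form up to floating-point error). Coefficients are reported in
#' both the standardized and the raw feature basis.
#'
#' @param x Per-cycle maximum Doppler frequency, Hz.
#' @param y Reference depth, cm.
#' @param order Polynomial order (default 2, a second-order model).
#' @return Object of class `polyreg_model` with `weights_raw`
#'   (intercept-first coefficients in the raw basis), `weights_std`,
#'   `center`, `scale`, `order` and the training `mse`.
#' @examples
#' m <- fit_polyreg(c(0, 1, 2), c(1, 2, 5))
#' m$weights_raw            # 1, 0, 1  (y = 1 + x^2)
#' predict(m, 2)            # 5
#' @export
fit_polyreg <- function(x, y, order = 2L) {
  stopifnot(length(x) == length(y), length(x) >= order + 1)
  if (length(unique(x)) < order + 1)
    stop(sprintf("rank-deficient design: need at least %d distinct x values for order %d",
                 order + 1, order), call. = FALSE)
  ctr <- mean(x)
  scl <- stats::sd(x)
  if (!is.finite(scl) || scl == 0) scl <- 1
  z <- (x - ctr) / scl
  Xz <- stats::poly(z, degree = order, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, Xz), y)
  wz <- unname(fit$coefficients)
  if (anyNA(wz))
    stop("rank-deficient design matrix: polynomial terms are collinear",
         call. = FALSE)
  # expand (z = (x - c)/s) back to raw-x coefficients via binomial expansion
  wr <- numeric(order + 1)
  for (k in 0:order) {
    for (j in 0:k) {
      wr[j + 1] <- wr[j + 1] +
        wz[k + 1] * choose(k, j) * (-ctr)^(k - j) / scl^k
    }
  }
  out <- list(order = as.integer(order), weights_std = wz, weights_raw = wr,
              center = ctr, scale = scl,
              mse = mean(fit$residuals^2))
  class(out) <- "polyreg_model"
  out
}

#' Predict depth from peak Doppler frequency
#'
#' @param object A `polyreg_model`.
#' @param newdata Numeric vector of maximum Doppler frequencies, Hz.
#' @param ... Unused.
#' @return Predicted depths, cm.
#' @export
predict.polyreg_model <- function(object, newdata, ...) {
  z <- (newdata - object$center) / object$scale
  drop(cbind(1, stats::poly(z, degree = object$order, raw = TRUE)) %*%
         object$weights_std)
}

#' @export
print.polyreg_model <- function(x, ...) {
  cat(sprintf("<polyreg_model order %d>  raw coefficients: %s  (train MSE %.4g)\n",
              x$order, paste(signif(x$weights_raw, 6), collapse = ", "), x$mse))
  invisible(x)
}
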