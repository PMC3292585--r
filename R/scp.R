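#' Analytic signal of a real feature series
#'
#' Frequency-domain construction of the analytic continuation
#' `x + i * H(x)`: positive frequencies are doubled, negative frequencies
#' zeroed, and the DC bin (plus the Nyquist bin for even length) kept, so the
#' imaginary part of the result is the discrete Hilbert transform of `x`.
#'
#' @param x real numeric vector, length >= 2, finite.
#' @return Complex vector of the same length; `Im(analytic_signal(x))` is the
#'   quadrature (Hilbert-transformed) series.
#' @export
analytic_signal <- function(x) {
  k <- length(x)
  if (k < 2L) stop("analytic_signal: need at least 2 points")
  if (anyNA(x) || any(!is.finite(x)))
    stop("analytic_signal: input contains NaN/Inf")
  h <- numeric(k)
  if (k %% 2L == 0L) {
    h[c(1L, k / 2L + 1L)] <- 1
    h[2L:(k / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((k + 1L) / 2L)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / k
}

#' Analytic representation of a two-row mixture
#'
#' Applies [analytic_signal()] to each row of the 2 x K mixture (reference
#' sample in row 1, test sample in row 2), over the feature axis in file
#' order.
#'
#' @param rows numeric 2 x K matrix.
#' @return An object of class `analytic_mixture`: list with `real_part` and
#'   `imag_part`, both 2 x K.
#' @export
analytic_mixture <- function(rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) != 2L) stop("analytic_mixture: expected exactly 2 rows")
  z1 <- analytic_signal(rows[1L, ])
  z2 <- analytic_signal(rows[2L, ])
  structure(list(real_part = rbind(Re(z1), Re(z2)),
                 imag_part = rbind(Im(z1), Im(z2))),
            class = "analytic_mixture")
}

#' Select single-component points by the directionality criterion
#'
#' A feature k is a single-component point (SCP) when the real and imaginary
#' 2-vectors of the analytic mixture at k point in (nearly) the same or
#' opposite direction: it is retained iff
#' `|R_k' I_k| / (||R_k|| * ||I_k||) >= cos(delta_theta)`. The absolute value
#' implements the "0 or pi radians" displacement rule. Features with a
#' zero-norm real or imaginary 2-vector are excluded from candidacy.
#'
#' @param mixture an [analytic_mixture()].
#' @param delta_theta angular tolerance in degrees, in (0, 90); the
#'   cross-validated grid is \{1, 3, 5\}.
#' @return An object of class `scp_set`: list with sorted unique `indices`
#'   (1-based feature indices) and `delta_theta`.
#' @export
select_scps <- function(mixture, delta_theta) {
  stopifnot(inherits(mixture, "analytic_mixture"))
  if (delta_theta <= 0 || delta_theta >= 90)
    stop("select_scps: delta_theta must be in (0, 90) degrees")
  R <- mixture$real_part
  I <- mixture$imag_part
  num <- abs(colSums(R * I))
  den <- sqrt(colSums(R^2)) * sqrt(colSums(I^2))
  ok <- den > 0
  ratio <- rep(0, ncol(R))
  ratio[ok] <- num[ok] / den[ok]
  idx <- which(ok & ratio >= cos(delta_theta * pi / 180))
  if (!length(idx))
    stop("no single-component points at delta_theta = ", delta_theta,
         " degrees (0 of ", ncol(R), " features); increase delta_theta")
  structure(list(indices = idx, delta_theta = delta_theta),
            class = "scp_set")
}
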