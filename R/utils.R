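#' Orientation wrapping helpers
#'
#' Orientations live on a 180-degree circle. `wrap_orientation()` maps angles
#' to the reporting convention `(-90, 90]` used throughout the package;
#' `orientation_difference()` returns the signed acute difference between two
#' orientations, also in `(-90, 90]`.
#'
#' @param theta orientation(s) in degrees.
#' @return numeric vector of wrapped angles in degrees.
#' @export
wrap_orientation <- function(theta) {
  w <- theta %% 180
  ifelse(w > 90, w - 180, w)
}

#' @rdname wrap_orientation
#' @param a,b orientations in degrees.
#' @export
orientation_difference <- function(a, b) {
  wrap_orientation(a - b)
}

#' Full width at half maximum of a Gaussian envelope
#'
#' Converts a Gaussian standard deviation to the full width at half maximum,
#' `2 sqrt(2 ln 2) sigma`. Used to relate the Gabor target's envelope sigma
#' (0.14 degrees by default in this package) to its FWHM description.
#'
#' @param sigma Gaussian standard deviation (any unit).
#' @return FWHM in the same unit.
#' @export
gaussian_fwhm <- function(sigma) {
  2 * sqrt(2 * log(2)) * sigma
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' generator functions are pure functions of their `seed` argument without
#' clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# per-trial substream seeds derived deterministically from a session seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# DFT sample frequencies in cycles per unit (d = sample spacing)
fft_freq <- function(n, d = 1) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

# separable Gaussian smoothing with edge renormalisation (non-circular)
gauss_smooth_mat <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k1 <- function(n) {
    w <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma_px)
    w / rowSums(w)
  }
  kr <- k1(nrow(m))
  kc <- k1(ncol(m))
  kr %*% m %*% t(kc)
}

# circular (FFT) Gaussian smoothing; fast path for noise synthesis where
# wrap-around edges are harmless
gauss_smooth_fft <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  fr <- fft_freq(nrow(m))
  fc <- fft_freq(ncol(m))
  # Fourier transform of a Gaussian kernel
  h <- exp(-2 * pi^2 * sigma_px^2 * outer(fr^2, fc^2, "+"))
  Re(stats::fft(stats::fft(m) * h, inverse = TRUE)) / length(m)
}

# circular correlation coefficient for orientation data (angle-doubled)
circular_orientation_cor <- function(theta1, theta2) {
  a <- 2 * theta1 * pi / 180
  b <- 2 * theta2 * pi / 180
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  num <- sum(sin(a - am) * sin(b - bm))
  den <- sqrt(sum(sin(a - am)^2) * sum(sin(b - bm)^2))
  if (den == 0) return(NA_real_)
  num / den
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
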