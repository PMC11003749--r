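#' Estimate global motion and pixelwise coupling coefficients
#'
#' Fits the separable motion model `I(x, t) = I0(x, t) + alpha(x) . v(t)`.
#' A single global translation `v(t)` per frame is estimated from the central
#' quarter of the image (half the linear extent in each dimension) against a
#' reference image (the mean of the pre-onset frames): an integer shift from
#' the FFT cross-correlation peak, refined to sub-pixel precision by a
#' gradient-based least-squares (Lucas-Kanade) step. The
#' coupling field `alpha(x)` is then the per-pixel least-squares regression of
#' intensity on the mean-centered `v(t)`; centering avoids absorbing the DC
#' image, since the model is only identified up to an additive constant in
#' `v`.
#'
#' @param stack a raw `vsd_stack` with at least 2 frames.
#' @param reference `"preonset"` (default) or `"mean"`: frames averaged into
#'   the registration reference.
#' @return an object of class `motion_trace`: `v` (T x 2 matrix, pixels),
#'   `alpha` (H x W x 2 array), `reference`.
#' @export
estimate_motion <- function(stack, reference = c("preonset", "mean")) {
  reference <- match.arg(reference)
  d <- dim(stack$frames)
  if (d[3] < 2) stopf("need at least 2 frames")
  tt <- frame_times(stack)
  ref_idx <- if (reference == "preonset" && any(tt <= 0)) {
    which(tt <= 0)
  } else {
    seq_len(d[3])
  }
  ref <- apply(stack$frames[, , ref_idx, drop = FALSE], c(1, 2), mean)

  # central quarter (half the linear size, centered)
  rsel <- seq(floor(d[1] / 4) + 1, floor(d[1] / 4) + floor(d[1] / 2))
  csel <- seq(floor(d[2] / 4) + 1, floor(d[2] / 4) + floor(d[2] / 2))
  refc <- ref[rsel, csel]
  refc <- refc - mean(refc)
  Fref <- stats::fft(refc)
  nr <- length(rsel); nc <- length(csel)
  g <- spatial_gradient(refc)
  # the reference image itself is a nuisance regressor: stimulus-evoked
  # fluorescence changes are (to first order) proportional to it, and must
  # not be read as translation
  gmat <- cbind(as.vector(g$row), as.vector(g$col), as.vector(refc))
  gg <- crossprod(gmat)

  v <- matrix(0, d[3], 2)
  if (stats::sd(refc) > 0 && rcond_safe(gg) > 1e-14) {
    for (t in seq_len(d[3])) {
      fr <- stack$frames[rsel, csel, t]
      fr <- fr - mean(fr)
      cc <- Re(stats::fft(Fref * Conj(stats::fft(fr)), inverse = TRUE))
      pk <- arrayInd(which.max(cc), dim(cc))
      s0 <- c(int_shift(pk[1], nr), int_shift(pk[2], nc))
      if (any(s0 != 0)) fr <- circ_shift(fr, -s0)
      # fr approx (1 + a) refc(x + dv): one least-squares step on the
      # reference gradient (plus the illumination term) recovers dv
      dv <- solve(gg, crossprod(gmat, as.vector(fr - refc)))
      v[t, ] <- s0 + dv[1:2]
    }
  }

  # alpha(x): per-pixel least squares on mean-centered v; pseudoinverse so
  # that purely 1-D motion (rank-deficient v) still identifies the coupling
  # within the spanned subspace
  vc <- sweep(v, 2, colMeans(v))
  alpha <- array(0, c(d[1], d[2], 2))
  xtx_pinv <- pinv_sym(crossprod(vc))
  if (!is.null(xtx_pinv)) {
    frames_mat <- matrix(stack$frames, d[1] * d[2], d[3])
    frames_mat <- frames_mat - rowMeans(frames_mat)
    coefs <- frames_mat %*% vc %*% xtx_pinv
    alpha[, , 1] <- matrix(coefs[, 1], d[1], d[2])
    alpha[, , 2] <- matrix(coefs[, 2], d[1], d[2])
  }
  structure(list(v = v, alpha = alpha, reference = reference),
            class = "motion_trace")
}

# Moore-Penrose inverse of a small symmetric PSD matrix; NULL if it is
# numerically zero
pinv_sym <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  tol <- max(e$values, 0) * 1e-10
  if (tol <= 0) return(NULL)
  keep <- e$values > tol
  e$vectors[, keep, drop = FALSE] %*%
    ((1 / e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
}

rcond_safe <- function(m) {
  out <- tryCatch(rcond(m), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}

# signed integer displacement from a circular correlation peak index
int_shift <- function(i, n) {
  s <- i - 1
  if (s > n / 2) s - n else s
}

# circular integer shift of a matrix by s = c(rows, cols)
circ_shift <- function(m, s) {
  n <- dim(m)
  ri <- ((seq_len(n[1]) - 1 - s[1]) %% n[1]) + 1
  ci <- ((seq_len(n[2]) - 1 - s[2]) %% n[2]) + 1
  m[ri, ci]
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames; |v| RMS %.3g px (ref: %s)\n",
              nrow(x$v), sqrt(mean(rowSums(x$v^2))), x$reference))
  invisible(x)
}

#' Remove the motion-related component from a stack
#'
#' Subtracts `alpha(x) . v(t)` (with `v` mean-centered, consistent with the
#' coupling fit) from every frame, leaving the motion-free component
#' `I0(x, t)`. Metadata are preserved.
#'
#' @param stack the `vsd_stack` the motion was estimated from.
#' @param motion a `motion_trace` from [estimate_motion()].
#' @return a stabilized `vsd_stack`.
#' @export
stabilize <- function(stack, motion) {
  d <- dim(stack$frames)
  if (nrow(motion$v) != d[3] || !all(dim(motion$alpha)[1:2] == d[1:2])) {
    stopf("motion trace geometry does not match stack")
  }
  vc <- sweep(motion$v, 2, colMeans(motion$v))
  out <- stack
  for (t in seq_len(d[3])) {
    out$frames[, , t] <- stack$frames[, , t] -
      motion$alpha[, , 1] * vc[t, 1] - motion$alpha[, , 2] * vc[t, 2]
  }
  out
}

#' Fractional fluorescence change (dF/F)
#'
#' `dF/F(t) = (F(t) - F0) / F0` with the baseline F0 the per-pixel average
#' over the stack's baseline window (-80 to 0 ms relative to onset by
#' default).
#'
#' @param stack a raw `vsd_stack`.
#' @return a `vsd_stack` with `is_dff = TRUE`.
#' @export
delta_f_over_f <- function(stack) {
  if (stack$is_dff) stopf("stack is already dF/F")
  idx <- frames_in_window(stack, stack$baseline_window)
  if (length(idx) < 1) stopf("baseline window covers no frames")
  f0 <- apply(stack$frames[, , idx, drop = FALSE], c(1, 2), mean)
  bad <- which(f0 <= 0)
  if (length(bad)) {
    stopf("baseline F0 <= 0 at %d pixel(s); first offenders (row,col): %s",
          length(bad),
          paste(apply(arrayInd(utils::head(bad, 3), dim(f0)), 1,
                      paste, collapse = ","), collapse = "; "))
  }
  out <- stack
  for (t in seq_len(dim(stack$frames)[3])) {
    out$frames[, , t] <- stack$frames[, , t] / f0 - 1
  }
  out$is_dff <- TRUE
  out
}

# annular frequency mask in cycles/mm with raised-cosine edges just outside
# the passband
bandpass_mask <- function(h, w, low, high, mm_per_pixel, edge_width) {
  fr <- fft_freq(h, mm_per_pixel)
  fc <- fft_freq(w, mm_per_pixel)
  rho <- sqrt(outer(fr^2, fc^2, "+"))
  m <- matrix(0, h, w)
  m[rho >= low & rho <= high] <- 1
  lo0 <- max(low - edge_width, 0)
  sel <- rho > lo0 & rho < low
  m[sel] <- 0.5 * (1 - cos(pi * (rho[sel] - lo0) / (low - lo0)))
  sel <- rho > high & rho < high + edge_width
  m[sel] <- 0.5 * (1 + cos(pi * (rho[sel] - high) / edge_width))
  m[1, 1] <- 0  # DC always removed
  m
}

#' Columnar-band spatial filter
#'
#' Bandpasses a 2D field (or every frame of a stack) to the spatial-frequency
#' band of the orientation columns, 0.8 to 3.0 cycles/mm by default, via an
#' annular frequency-domain mask with raised-cosine edges of `edge_width`
#' cycles/mm to limit ringing. The DC component is always removed, so the
#' output has approximately zero mean.
#'
#' @param x a numeric matrix or a `vsd_stack`.
#' @param low,high band edges in cycles/mm.
#' @param mm_per_pixel pixel pitch in mm; taken from the stack if absent.
#' @param edge_width raised-cosine edge width in cycles/mm.
#' @return an object of the same type as `x`.
#' @export
bandpass_columnar <- function(x, low = 0.8, high = 3.0, mm_per_pixel = NULL,
                              edge_width = 0.1) {
  if (inherits(x, "vsd_stack")) {
    mpp <- if (is.null(mm_per_pixel)) x$mm_per_pixel else mm_per_pixel
    if (!is.finite(mpp)) stopf("stack carries no mm_per_pixel")
    d <- dim(x$frames)
    m <- bandpass_check_mask(d[1], d[2], low, high, mpp, edge_width)
    out <- x
    for (t in seq_len(d[3])) {
      out$frames[, , t] <- Re(stats::fft(stats::fft(x$frames[, , t]) * m,
                                         inverse = TRUE)) / (d[1] * d[2])
    }
    return(out)
  }
  if (is.null(mm_per_pixel)) stopf("mm_per_pixel required for matrix input")
  m <- bandpass_check_mask(nrow(x), ncol(x), low, high, mm_per_pixel,
                           edge_width)
  Re(stats::fft(stats::fft(x) * m, inverse = TRUE)) / length(x)
}

bandpass_check_mask <- function(h, w, low, high, mpp, edge_width) {
  nyq <- 1 / (2 * mpp)
  if (!(low < high)) stopf("low must be < high")
  if (high > nyq) stopf("high %.3g cycles/mm exceeds Nyquist %.3g", high, nyq)
  bandpass_mask(h, w, low, high, mpp, edge_width)
}

#' Extract the response at the flash frequency
#'
#' For fixation-block recordings in which the stimulus is flashed at 5 Hz,
#' computes the per-pixel Fourier amplitude and phase at the flash frequency
#' over the stimulation window (onset to the end of the flash train). The
#' window is truncated to a whole number of flash periods so the amplitude is
#' invariant to the flash's temporal phase. Amplitude is reported so that a
#' pixel following `a sin(2 pi f t)` yields `a`.
#'
#' @param stack a dF/F `vsd_stack`.
#' @param flash_frequency Hz.
#' @param window ms pair of the stimulation window relative to onset;
#'   defaults to onset through 1000 ms (one flash train).
#' @return an object of class `flash_map` with `amplitude`, `phase` (radians)
#'   and `flash_frequency`.
#' @export
extract_flash_response <- function(stack, flash_frequency = 5,
                                   window = c(0, 1000)) {
  idx <- frames_in_window(stack, window)
  period_frames <- stack$frame_rate / flash_frequency
  n_cycles <- floor(length(idx) / period_frames)
  if (n_cycles < 2) {
    stopf("window of %d frames does not resolve %g Hz (need >= 2 periods)",
          length(idx), flash_frequency)
  }
  n <- as.integer(round(n_cycles * period_frames))
  idx <- idx[seq_len(n)]
  d <- dim(stack$frames)
  mat <- matrix(stack$frames[, , idx], d[1] * d[2], n)
  tph <- 2 * pi * flash_frequency * (seq_len(n) - 1) / stack$frame_rate
  co <- mat %*% cos(tph)
  si <- mat %*% sin(tph)
  amp <- 2 / n * sqrt(co^2 + si^2)
  ph <- atan2(si, co)
  structure(list(amplitude = matrix(amp, d[1], d[2]),
                 phase = matrix(ph, d[1], d[2]),
                 flash_frequency = flash_frequency,
                 mm_per_pixel = stack$mm_per_pixel),
            class = "flash_map")
}

#' @export
print.flash_map <- function(x, ...) {
  cat(sprintf("<flash_map> %dx%d px at %g Hz; peak amplitude %.3g\n",
              nrow(x$amplitude), ncol(x$amplitude), x$flash_frequency,
              max(x$amplitude)))
  invisible(x)
}
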