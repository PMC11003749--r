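#' Complex population vector of a 12-channel tuning curve
#'
#' Sums the channel responses with angle-doubled phases,
#' `z = sum_k r_k exp(2 i theta_k)`. The decoded orientation is `arg(z)/2`
#' mapped to `(-90, 90]`, the magnitude is `|z|`, and the coherence is the
#' normalized amplitude `|z| / sum_k |r_k|` in `[0, 1]` (the tuning strength
#' relative to the total channel activation). Missing channels (`NA`) are
#' dropped; if all channels are missing the result is flagged undefined.
#' Negative channel values are retained: they rotate the vector by 90 deg,
#' consistent with the balanced positive/negative decomposition of a
#' zero-mean columnar field.
#'
#' @param tuning numeric vector of channel responses.
#' @param channels channel center orientations in degrees.
#' @return list with `magnitude`, `angle` (degrees), `coherence`, `defined`.
#' @export
population_vector <- function(tuning, channels = seq(-75, 90, by = 15)) {
  if (length(tuning) != length(channels)) {
    stopf("tuning and channels lengths differ")
  }
  ok <- is.finite(tuning)
  if (!any(ok)) {
    return(list(magnitude = NA_real_, angle = NA_real_,
                coherence = NA_real_, defined = FALSE))
  }
  z <- sum(tuning[ok] * exp(2i * channels[ok] * pi / 180))
  denom <- sum(abs(tuning[ok]))
  list(magnitude = Mod(z),
       angle = wrap_orientation(Arg(z) / 2 * 180 / pi),
       coherence = if (denom > 0) Mod(z) / denom else 0,
       defined = TRUE)
}

#' Target-evoked response series
#'
#' The target-evoked response in the presence of a background: the frame-wise
#' (and channel-wise) difference between the condition-mean response to
#' target-plus-background and the condition-mean response to the background
#' alone (the "delta TBg" convention).
#'
#' @param tb `decoded_series` for the target-plus-background condition mean.
#' @param b `decoded_series` for the matched background-only condition mean.
#' @return a `decoded_series` of the same shape.
#' @export
target_evoked_series <- function(tb, b) {
  if (!identical(dim(tb$values), dim(b$values)) ||
      length(tb$times) != length(b$times) ||
      max(abs(tb$times - b$times)) > 1e-9 ||
      !identical(tb$scale, b$scale)) {
    stopf("series are not on matched conditions/frame grids")
  }
  out <- tb
  out$values <- tb$values - b$values
  out
}

#' Population-vector trajectory of a 12-channel series
#'
#' Reduces a population `decoded_series` to its per-frame population vector:
#' magnitude, angle and coherence, with the decoded peak orientation masked
#' wherever the coherence (normalized vector amplitude) does not exceed
#' `coherence_threshold`.
#'
#' @param series a population `decoded_series` (T x 12 values).
#' @param coherence_threshold fraction in `(0, 1)`; 0.2 by default.
#' @return an object of class `pop_trajectory`: a data.frame with columns
#'   `t_ms`, `magnitude`, `angle_deg`, `coherence`, `masked`.
#' @export
trajectory_summary <- function(series, coherence_threshold = 0.2) {
  if (!is.matrix(series$values)) stopf("series is not a population series")
  if (coherence_threshold < 0 || coherence_threshold >= 1) {
    stopf("coherence_threshold must lie in [0, 1)")
  }
  ch <- series$channels
  rows <- lapply(seq_len(nrow(series$values)), function(i) {
    pv <- population_vector(series$values[i, ], ch)
    data.frame(t_ms = series$times[i], magnitude = pv$magnitude,
               angle_deg = pv$angle, coherence = pv$coherence,
               masked = !isTRUE(pv$defined) ||
                 !(pv$coherence > coherence_threshold))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pop_trajectory", "data.frame")
  attr(out, "coherence_threshold") <- coherence_threshold
  out
}

#' @export
print.pop_trajectory <- function(x, ...) {
  cat(sprintf("<pop_trajectory> %d frames, %d above coherence %.2g\n",
              nrow(x), sum(!x$masked), attr(x, "coherence_threshold")))
  NextMethod()
}

#' Polar plot of a population trajectory
#'
#' Draws the trajectory in the polar space spanned by the 12 orientation
#' channels (angle doubled so that the 180-deg orientation circle covers the
#' full plot circle); trajectories commence at the origin at stimulus onset.
#'
#' @param x a `pop_trajectory`.
#' @param from_ms first frame time to draw.
#' @param ... passed to [graphics::lines()].
#' @export
plot.pop_trajectory <- function(x, from_ms = 0, ...) {
  sel <- x$t_ms >= from_ms & is.finite(x$magnitude)
  r <- x$magnitude[sel]
  a <- 2 * x$angle_deg[sel] * pi / 180
  lim <- max(r, 1e-9) * 1.05
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "0 - 90 axis", ylab = "45 - -45 axis")
  phi <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(lim * cos(phi), lim * sin(phi), col = "grey80")
  graphics::lines(r * cos(a), r * sin(a), ...)
  graphics::points(0, 0, pch = 16, cex = 0.6)
  invisible(x)
}
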