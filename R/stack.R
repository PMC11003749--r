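#' Fluorescence image stack
#'
#' The basic imaging container: a height x width x time array of camera-unit
#' fluorescence (or unitless dF/F after [delta_f_over_f()]), with the frame
#' rate, the index of the stimulus-onset frame, and the baseline window used
#' for dF/F normalization. Frame times are reported in ms relative to onset;
#' the onset frame itself is at t = 0.
#'
#' @param frames numeric array `H x W x T`.
#' @param frame_rate acquisition rate in Hz.
#' @param onset_index index (1-based) of the stimulus-onset frame.
#' @param is_dff logical; `TRUE` once frames are fractional dF/F.
#' @param baseline_window ms pair relative to onset over which the baseline
#'   fluorescence F0 is averaged.
#' @param mm_per_pixel optional pixel pitch in mm, carried for spatial
#'   filtering.
#' @return an object of class `vsd_stack`.
#' @export
image_stack <- function(frames, frame_rate = 100, onset_index = 21,
                        is_dff = FALSE, baseline_window = c(-80, 0),
                        mm_per_pixel = NA_real_) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stopf("frames must be an H x W x T array")
  }
  if (onset_index < 1 || onset_index > dim(frames)[3]) {
    stopf("onset_index %d outside 1..%d", onset_index, dim(frames)[3])
  }
  if (frame_rate <= 0) stopf("frame_rate must be positive")
  structure(
    list(frames = frames, frame_rate = frame_rate,
         onset_index = as.integer(onset_index), is_dff = isTRUE(is_dff),
         baseline_window = baseline_window, mm_per_pixel = mm_per_pixel),
    class = "vsd_stack")
}

#' Frame times of a stack in ms relative to stimulus onset
#' @param stack a `vsd_stack`.
#' @return numeric vector, one entry per frame.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[3]) - stack$onset_index) * 1000 / stack$frame_rate
}

#' @export
print.vsd_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<vsd_stack> %dx%d px, %d frames @ %g Hz, onset frame %d (%s)\n",
              d[1], d[2], d[3], x$frame_rate, x$onset_index,
              if (x$is_dff) "dF/F" else "raw fluorescence"))
  invisible(x)
}

#' Downsample a stack by block averaging
#'
#' Spatial block means (e.g. 512 -> 128 with `factor = 4`), chosen for its
#' noise-averaging property. The pixel pitch, when known, is scaled
#' accordingly.
#'
#' @param stack a `vsd_stack`.
#' @param factor integer block size; must divide both spatial dimensions.
#' @return a `vsd_stack` at reduced resolution.
#' @export
downsample_stack <- function(stack, factor = 4) {
  d <- dim(stack$frames)
  if (factor == 1) return(stack)
  if (d[1] %% factor != 0 || d[2] %% factor != 0) {
    stopf("factor %d does not divide grid %dx%d", factor, d[1], d[2])
  }
  h <- d[1] / factor; w <- d[2] / factor
  out <- array(0, c(h, w, d[3]))
  for (t in seq_len(d[3])) {
    m <- stack$frames[, , t]
    dim(m) <- c(factor, h, factor, w)
    out[, , t] <- apply(m, c(2, 4), mean)
  }
  s <- stack
  s$frames <- out
  s$mm_per_pixel <- stack$mm_per_pixel * factor
  s
}

# indices of frames whose time lies in [window[1], window[2]] ms
frames_in_window <- function(stack, window) {
  tt <- frame_times(stack)
  which(tt >= window[1] & tt <= window[2])
}
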