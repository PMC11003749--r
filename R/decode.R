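#' Fit the retinotopic template
#'
#' Nonlinear least-squares fit of an elliptical 2D Gaussian with offset to the
#' flash-response amplitude map of the target, initialized from image
#' moments. The rendered Gaussian (offset excluded) is the retinotopic
#' template H_ret used by the decoders.
#'
#' @param amplitude a `flash_map` or a numeric amplitude matrix.
#' @param mm_per_pixel pixel pitch; taken from the flash map if absent.
#' @return an object of class `ret_template`: `params` (center row/col in
#'   pixels, sigma_major/sigma_minor in mm, rotation in degrees, amplitude,
#'   offset), `h_ret` (rendered field), `mm_per_pixel`.
#' @export
fit_retinotopic_template <- function(amplitude, mm_per_pixel = NULL) {
  if (inherits(amplitude, "flash_map")) {
    if (is.null(mm_per_pixel)) mm_per_pixel <- amplitude$mm_per_pixel
    amplitude <- amplitude$amplitude
  }
  if (is.null(mm_per_pixel) || !is.finite(mm_per_pixel)) mm_per_pixel <- 1
  h <- nrow(amplitude); w <- ncol(amplitude)
  rng <- range(amplitude)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) {
    stopf("amplitude map is flat; no retinotopic response to fit")
  }

  # moment initialization on the offset-subtracted map
  a0 <- pmax(amplitude - stats::quantile(amplitude, 0.25), 0)
  tot <- sum(a0)
  rr <- row(amplitude); cc <- col(amplitude)
  mr <- sum(rr * a0) / tot; mc <- sum(cc * a0) / tot
  vr <- sum((rr - mr)^2 * a0) / tot
  vc <- sum((cc - mc)^2 * a0) / tot
  vrc <- sum((rr - mr) * (cc - mc) * a0) / tot

  zv <- as.vector(amplitude)
  rv <- as.vector(rr)
  cv <- as.vector(cc)
  # quadratic-form parameterization (exp(-(qa u^2 + 2 qb u v + qc v^2))):
  # regular even for isotropic Gaussians, where an explicit rotation
  # parameter is unidentifiable
  vr <- max(vr, 0.5); vc <- max(vc, 0.5)
  dd <- max(vr * vc - vrc^2, 0.25)
  model_val <- function(p) {
    p[["off"]] + p[["amp"]] *
      exp(-(p[["qa"]] * (rv - p[["r0"]])^2 +
              2 * p[["qb"]] * (rv - p[["r0"]]) * (cv - p[["c0"]]) +
              p[["qc"]] * (cv - p[["c0"]])^2))
  }
  start <- c(r0 = mr, c0 = mc, qa = vc / (2 * dd), qb = -vrc / (2 * dd),
             qc = vr / (2 * dd), amp = max(amplitude) - min(amplitude),
             off = min(amplitude))
  fit <- minpack.lm::nls.lm(
    par = start, fn = function(p) zv - model_val(p),
    lower = c(r0 = 1, c0 = 1, qa = 1e-8, qb = -Inf, qc = 1e-8, amp = 0,
              off = -Inf),
    upper = c(r0 = h, c0 = w, qa = Inf, qb = Inf, qc = Inf, amp = Inf,
              off = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- fit$par

  # canonical ellipse: eigen-decomposition of the quadratic form
  q <- matrix(c(cf[["qa"]], cf[["qb"]], cf[["qb"]], cf[["qc"]]), 2, 2)
  e <- eigen(q, symmetric = TRUE)
  lam <- pmax(e$values, 1e-12)
  sr <- 1 / sqrt(2 * lam[2])       # larger sigma from the smaller eigenvalue
  sc <- 1 / sqrt(2 * lam[1])
  rot <- wrap_orientation(atan2(e$vectors[2, 2], e$vectors[1, 2]) * 180 / pi)

  rend <- matrix(model_val(cf), h, w) - cf[["off"]]
  structure(
    list(params = list(center = c(cf[["r0"]], cf[["c0"]]),
                       sigma_major_mm = sr * mm_per_pixel,
                       sigma_minor_mm = sc * mm_per_pixel,
                       sigma_major_px = sr, sigma_minor_px = sc,
                       rotation_deg = rot, amplitude = cf[["amp"]],
                       offset = cf[["off"]]),
         h_ret = rend, mm_per_pixel = mm_per_pixel),
    class = "ret_template")
}

#' @export
print.ret_template <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<ret_template> center (%.1f, %.1f) px; sigma %.2f x %.2f mm at %.0f deg; amp %.3g, offset %.3g\n",
    p$center[1], p$center[2], p$sigma_major_mm, p$sigma_minor_mm,
    p$rotation_deg, p$amplitude, p$offset))
  invisible(x)
}

#' @export
coef.ret_template <- function(object, ...) {
  p <- object$params
  c(center_row = p$center[1], center_col = p$center[2],
    sigma_major_mm = p$sigma_major_mm, sigma_minor_mm = p$sigma_minor_mm,
    rotation_deg = p$rotation_deg, amplitude = p$amplitude, offset = p$offset)
}

# mask of pixels within n_sd standard deviations of the template ellipse
template_ellipse_mask <- function(template, n_sd = 2) {
  p <- template$params
  h <- nrow(template$h_ret); w <- ncol(template$h_ret)
  rr <- row(template$h_ret) - p$center[1]
  cc <- col(template$h_ret) - p$center[2]
  th <- p$rotation_deg * pi / 180
  u <- (rr * cos(th) + cc * sin(th)) / p$sigma_major_px
  v <- (-rr * sin(th) + cc * cos(th)) / p$sigma_minor_px
  u^2 + v^2 <= n_sd^2
}

#' Build the columnar orientation map from grating responses
#'
#' Estimates each pixel's orientation preference from the bandpassed 5 Hz
#' grating flash responses by the angle-doubled vector sum
#' `z(x) = sum_k resp_k(x) exp(2 i theta_k)`; the columnar magnitude is
#' `A = |z|` and the preference `theta = arg(z) / 2`. The complex columnar
#' template is `H_ori = H_ret A exp(2 i theta)`, windowed to the pixels
#' within `window_sd` standard deviations of the retinotopic ellipse, and
#' partitioned into 12 non-negative population fields `H_theta` (bins
#' centered -75 to 90 deg in 15 deg steps, half-width 7.5 deg, edge pixels
#' assigned to the lower bin), each normalized to unit summed magnitude so
#' every sub-population is equally represented.
#'
#' @param grating_amps list of `flash_map`s (or matrices), one per grating
#'   orientation.
#' @param orientations grating orientations in degrees, spanning 180.
#' @param template a [fit_retinotopic_template()] result.
#' @param mm_per_pixel pixel pitch; needed if `grating_amps` are matrices.
#' @param band columnar spatial-frequency band, cycles/mm.
#' @param window_sd retinotopic inclusion window, in template SDs.
#' @param bandpass apply the columnar bandpass to each grating response
#'   (disable for inputs already in the columnar band).
#' @return an object of class `columnar_map`: fields `A`, `theta`, `h_ori`
#'   (complex), `partitions` (list of 12 weight matrices or `NULL` when a bin
#'   is empty), `mask`, `channels`.
#' @export
fit_columnar_map <- function(grating_amps, orientations, template,
                             mm_per_pixel = NULL, band = c(0.8, 3.0),
                             window_sd = 2, bandpass = TRUE) {
  if (length(grating_amps) != length(orientations)) {
    stopf("one grating response per orientation required")
  }
  if (length(orientations) < 3) {
    stopf("need at least 3 grating orientations; got %d",
          length(orientations))
  }
  mats <- lapply(grating_amps, function(g) {
    if (inherits(g, "flash_map")) {
      if (is.null(mm_per_pixel)) mm_per_pixel <<- g$mm_per_pixel
      g$amplitude
    } else g
  })
  if (is.null(mm_per_pixel) || !is.finite(mm_per_pixel)) {
    stopf("mm_per_pixel unknown; pass it explicitly")
  }
  if (bandpass) {
    mats <- lapply(mats, bandpass_columnar, low = band[1], high = band[2],
                   mm_per_pixel = mm_per_pixel)
  }
  z <- Reduce(`+`, Map(function(m, o) m * exp(2i * o * pi / 180),
                       mats, orientations))
  A <- Mod(z)
  theta <- (Arg(z) / 2 * 180 / pi) %% 180
  h_ori <- template$h_ret * A * exp(2i * theta * pi / 180)
  mask <- template_ellipse_mask(template, window_sd)

  channels <- seq(-75, 90, by = 15)
  partitions <- vector("list", length(channels))
  magn <- Mod(h_ori)
  # wrap preference into (-82.5, 97.5]; bin j covers (c_j - 7.5, c_j + 7.5]
  thw <- theta
  thw[thw > 97.5] <- thw[thw > 97.5] - 180
  bin <- ceiling((thw + 82.5) / 15)
  bin[bin == 0] <- 12  # exactly -82.5 wraps to the 90-deg bin's lower edge
  for (j in seq_along(channels)) {
    sel <- mask & bin == j
    if (!any(sel)) next
    wfield <- matrix(0, nrow(theta), ncol(theta))
    wfield[sel] <- magn[sel]
    s <- sum(wfield)
    if (s > 0) partitions[[j]] <- wfield / s
  }
  structure(list(A = A, theta = theta, h_ori = h_ori,
                 partitions = partitions, mask = mask, channels = channels,
                 mm_per_pixel = mm_per_pixel, band = band,
                 window_sd = window_sd),
            class = "columnar_map")
}

#' @export
print.columnar_map <- function(x, ...) {
  n_missing <- sum(vapply(x$partitions, is.null, logical(1)))
  cat(sprintf(
    "<columnar_map> %dx%d px; %d/%d channels populated; %d px in window\n",
    nrow(x$theta), ncol(x$theta), length(x$channels) - n_missing,
    length(x$channels), sum(x$mask)))
  invisible(x)
}

#' Pixelwise residual variance maps
#'
#' Reliability weights for the decoders: the per-pixel variance of
#' condition-mean-subtracted residuals, taken across all frames and trials.
#' For the columnar scale the residuals are computed on bandpassed frames.
#' Variances are floored at the `floor_quantile` quantile of the positive
#' values to keep the reliability weights bounded at quiet pixels.
#'
#' @param stacks list of dF/F `vsd_stack`s, one per trial, same geometry.
#' @param condition_labels factor-like vector, one label per trial.
#' @param scale `"retinotopic"` or `"columnar"`.
#' @param band,mm_per_pixel columnar bandpass parameters.
#' @param floor_quantile variance floor quantile.
#' @return an object of class `variance_maps` with `sigma2` and `scale`.
#' @export
estimate_pixel_variance <- function(stacks, condition_labels,
                                    scale = c("retinotopic", "columnar"),
                                    band = c(0.8, 3.0), mm_per_pixel = NULL,
                                    floor_quantile = 0.01) {
  scale <- match.arg(scale)
  if (length(stacks) != length(condition_labels)) {
    stopf("one condition label per stack required")
  }
  conds <- split(seq_along(stacks), condition_labels)
  usable <- Filter(function(ix) length(ix) >= 2, conds)
  if (!length(usable)) stopf("no condition has >= 2 trials")

  d <- dim(stacks[[1]]$frames)
  ss <- matrix(0, d[1], d[2])
  dof <- 0
  for (ix in usable) {
    arrs <- lapply(stacks[ix], function(s) {
      if (scale == "columnar") {
        s <- bandpass_columnar(s, low = band[1], high = band[2],
                               mm_per_pixel = mm_per_pixel)
      }
      s$frames
    })
    msum <- Reduce(`+`, arrs) / length(arrs)
    for (a in arrs) {
      r <- a - msum
      ss <- ss + rowSums(r^2, dims = 2)
    }
    dof <- dof + (length(ix) - 1) * d[3]
  }
  sigma2 <- ss / dof
  pos <- sigma2[sigma2 > 0]
  if (!length(pos)) stopf("all residual variances are zero")
  fl <- stats::quantile(pos, floor_quantile)
  sigma2 <- pmax(sigma2, fl)
  structure(list(sigma2 = sigma2, scale = scale, floor = fl),
            class = "variance_maps")
}

#' Decoded time series container
#'
#' @param values numeric vector (scalar decoders) or T x 12 matrix
#'   (population decoder); `NA` columns mark missing channels.
#' @param times frame times in ms relative to onset.
#' @param scale label: `"retinotopic"`, `"axis_0_90"`, or `"population"`.
#' @param channels channel center orientations for population series.
#' @param units unit label (`"template"` before, `"zscore"` after
#'   normalization).
#' @return an object of class `decoded_series`.
#' @export
decoded_series <- function(values, times, scale, channels = NULL,
                           units = "template") {
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (n != length(times)) stopf("one value (or row) per frame required")
  structure(list(values = values, times = times, scale = scale,
                 channels = channels, units = units),
            class = "decoded_series")
}

#' @export
print.decoded_series <- function(x, ...) {
  cat(sprintf("<decoded_series> %s, %d frames (%s)\n", x$scale,
              length(x$times), x$units))
  invisible(x)
}

# shared projection core: frame-by-frame inner product with a reliability
# weighted template. Scalar decoders normalize by the Euclidean norm of the
# weighted template (projection convention); the population channels
# normalize by its absolute sum, making each channel the reliability-weighted
# mean over its pixel subset so every sub-population is equally represented.
project_stack <- function(stack, template_field, sigma2, mask = NULL,
                          norm = c("euclidean", "sum")) {
  norm <- match.arg(norm)
  w <- template_field
  if (!is.null(sigma2)) w <- w / sigma2
  if (!is.null(mask)) w[!mask] <- 0
  nrm <- if (norm == "euclidean") sqrt(sum(Mod(w)^2)) else sum(Mod(w))
  if (nrm == 0) return(rep(NA_real_, dim(stack$frames)[3]))
  d <- dim(stack$frames)
  as.vector(crossprod(matrix(stack$frames, d[1] * d[2], d[3]),
                      as.vector(Re(w)))) / nrm
}

#' Retinotopic-scale decoder
#'
#' Per frame, the inner product of the dF/F image with the reliability
#' weighted retinotopic template `H_ret / sigma_ret^2`, normalized by the
#' Euclidean norm of the weighted template. With uniform variance this
#' reduces to the plain template projection.
#'
#' @param stack a dF/F `vsd_stack`.
#' @param template a `ret_template`.
#' @param var a `variance_maps` of retinotopic scale, or `NULL` for uniform
#'   weighting.
#' @return a `decoded_series` (scalar per frame).
#' @export
decode_retinotopic <- function(stack, template, var = NULL) {
  sigma2 <- variance_field(var, "retinotopic")
  vals <- project_stack(stack, template$h_ret, sigma2)
  decoded_series(vals, frame_times(stack), "retinotopic")
}

variance_field <- function(var, expected_scale) {
  if (is.null(var)) return(NULL)
  if (!inherits(var, "variance_maps")) stopf("var must be a variance_maps")
  if (var$scale != expected_scale) {
    stopf("variance maps are %s-scale; %s-scale required", var$scale,
          expected_scale)
  }
  var$sigma2
}

#' Columnar 0-90 axis decoder
#'
#' Projects bandpassed frames onto the real part of the complex columnar
#' template, reliability-weighted by the columnar residual variance. Positive
#' output means relatively stronger activation of neurons tuned to the target
#' orientation (0 deg); negative means the orthogonal orientation (90 deg).
#'
#' @param stack a dF/F `vsd_stack`; bandpassed to the columnar band first
#'   unless `bandpassed = TRUE`.
#' @param cmap a `columnar_map`.
#' @param var columnar-scale `variance_maps` or `NULL`.
#' @param bandpassed set `TRUE` if the stack is already in the columnar band.
#' @return a `decoded_series` (scalar per frame).
#' @export
decode_columnar_axis <- function(stack, cmap, var = NULL,
                                 bandpassed = FALSE) {
  if (!bandpassed) {
    stack <- bandpass_columnar(stack, low = cmap$band[1], high = cmap$band[2],
                               mm_per_pixel = cmap$mm_per_pixel)
  }
  sigma2 <- variance_field(var, "columnar")
  vals <- project_stack(stack, Re(cmap$h_ori), sigma2, cmap$mask)
  decoded_series(vals, frame_times(stack), "axis_0_90")
}

#' 12-channel population decoder
#'
#' One output per orientation bin and frame: the bandpassed frame projected
#' onto that bin's reliability-weighted population field
#' `H_theta / sigma_col^2`, normalized by the field's summed magnitude —
#' i.e. each channel is the reliability-weighted mean of the columnar-band
#' activity over its pixel subset, so every sub-population is equally
#' represented in the tuning curve. Channels whose
#' orientation bin contains no pixels are reported as `NA` and excluded
#' downstream rather than zero-filled.
#'
#' @inheritParams decode_columnar_axis
#' @return a `decoded_series` whose `values` is a T x 12 matrix.
#' @export
decode_population <- function(stack, cmap, var = NULL, bandpassed = FALSE) {
  if (!bandpassed) {
    stack <- bandpass_columnar(stack, low = cmap$band[1], high = cmap$band[2],
                               mm_per_pixel = cmap$mm_per_pixel)
  }
  sigma2 <- variance_field(var, "columnar")
  nt <- dim(stack$frames)[3]
  out <- matrix(NA_real_, nt, length(cmap$channels))
  colnames(out) <- cmap$channels
  for (j in seq_along(cmap$channels)) {
    if (is.null(cmap$partitions[[j]])) next
    out[, j] <- project_stack(stack, cmap$partitions[[j]], sigma2, cmap$mask,
                              norm = "sum")
  }
  decoded_series(out, frame_times(stack), "population",
                 channels = cmap$channels)
}
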