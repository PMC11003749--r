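#' Parameters of the delayed divisive-normalization population model
#'
#' The model simulates 12 orientation-tuned columnar channels (preferred
#' orientations -75 to 90 deg in 15 deg steps). The stimulus drives, for each
#' channel, an excitation signal and a normalization signal, each linear in
#' stimulus contrast, obtained by convolving an effective-contrast field with
#' a separable spatiotemporal impulse response (2D Gaussian in space, gamma
#' density in time) and evaluating at the stimulus center. The channel
#' response is `r = r_e^p / (r_n^p + r0^p)`. The normalization pathway is
#' more broadly orientation tuned (`sigma_n > sigma_e`) and temporally slower
#' (`a_n b_n > a_e b_e`); these two properties produce, respectively, the
#' orientation-dependent late masking and the biphasic dynamics.
#'
#' Defaults are the reference parameter set: `p = 2`, `r0 = 0.03125`,
#' excitation `(sigma_e = 15 deg, s_e = 0.28 deg, a_e = 9, b_e = 8 ms)`,
#' normalization `(sigma_n = 20 deg, s_n = 0.28 deg, a_n = 9,
#' b_n = 10.64 ms)`. `sigma_n = Inf` is accepted and gives an
#' orientation-untuned (flat) normalization pool, the control that removes
#' the late similarity-masking phase.
#'
#' @param p response exponent.
#' @param r0 normalization constant (effective-contrast units).
#' @param sigma_e,s_e,a_e,b_e excitation orientation-tuning SD (deg), spatial
#'   pooling SD (deg), gamma shape, gamma scale (ms).
#' @param sigma_n,s_n,a_n,b_n the same for the normalization signal.
#' @param dt simulation step, ms.
#' @param t_max simulation horizon, ms.
#' @param grid_step,grid_half spatial grid: sample spacing and half-extent in
#'   degrees.
#' @param channels channel preferred orientations, degrees.
#' @param frame_ms output frame duration for box-averaging (10 ms mirrors the
#'   imaging frame rate); frames are stamped at the end of their bin.
#' @return an object of class `norm_model_params`.
#' @export
norm_model_params <- function(p = 2, r0 = 0.03125,
                              sigma_e = 15, s_e = 0.28, a_e = 9, b_e = 8,
                              sigma_n = 20, s_n = 0.28, a_n = 9, b_n = 10.64,
                              dt = 1, t_max = 400, grid_step = 0.02,
                              grid_half = 3,
                              channels = seq(-75, 90, by = 15),
                              frame_ms = 10) {
  for (nm in c("p", "r0", "sigma_e", "s_e", "a_e", "b_e", "s_n", "a_n",
               "b_n", "dt", "t_max", "grid_step", "grid_half", "frame_ms")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) stopf("%s must be a positive number", nm)
  }
  if (!(sigma_n > 0)) stopf("sigma_n must be positive (Inf allowed)")
  if (dt > b_e / 4 || dt > b_n / 4) {
    stopf("dt = %g ms too coarse for gamma scales (need dt <= b/4)", dt)
  }
  structure(list(p = p, r0 = r0,
                 omega_e = list(sigma = sigma_e, s = s_e, a = a_e, b = b_e),
                 omega_n = list(sigma = sigma_n, s = s_n, a = a_n, b = b_n),
                 dt = dt, t_max = t_max, grid_step = grid_step,
                 grid_half = grid_half, channels = channels,
                 frame_ms = frame_ms),
            class = "norm_model_params")
}

#' @export
print.norm_model_params <- function(x, ...) {
  cat(sprintf(
    "<norm_model_params> p=%g r0=%g | exc: sigma=%g deg s=%g deg gamma(%g,%g ms) | norm: sigma=%g deg s=%g deg gamma(%g,%g ms)\n",
    x$p, x$r0, x$omega_e$sigma, x$omega_e$s, x$omega_e$a, x$omega_e$b,
    x$omega_n$sigma, x$omega_n$s, x$omega_n$a, x$omega_n$b))
  invisible(x)
}

# orientation tuning factor with wrapping to the acute difference
orientation_factor <- function(delta, sigma) {
  if (!is.finite(sigma)) return(rep(1, length(delta)))
  exp(-wrap_orientation(delta)^2 / (2 * sigma^2))
}

#' Separable spatiotemporal impulse response
#'
#' The product of a unit-integral 2D Gaussian (SD `s` degrees) and a
#' unit-integral gamma density (shape `a`, scale `b` ms), discretized on the
#' model grids. The temporal kernel is evaluated at bin midpoints, truncated
#' where the tail falls below 1e-6 of the peak, and renormalized to unit sum;
#' the 1D spatial kernel is normalized to unit sum so that separable spatial
#' pooling has unit mass.
#'
#' @param s spatial SD, degrees.
#' @param a,b gamma shape and scale (ms).
#' @param dt time step, ms.
#' @param grid_step,grid_half spatial discretization, degrees.
#' @return an object of class `model_kernel`: `spatial` (1D unit-sum
#'   vector), `spatial_x` (its sample positions), `temporal` (unit-sum
#'   vector), `temporal_t` (bin midpoints, ms).
#' @export
impulse_kernel <- function(s, a, b, dt = 1, grid_step = 0.02,
                           grid_half = 3) {
  if (dt > b / 4) stopf("dt = %g does not resolve gamma scale b = %g", dt, b)
  tmid <- seq(dt / 2, by = dt, length.out = ceiling(12 * a * b / dt))
  kt <- stats::dgamma(tmid, shape = a, scale = b) * dt
  keep <- max(which(kt > 1e-6 * max(kt)))
  kt <- kt[seq_len(keep)]
  kt <- kt / sum(kt)
  xs <- seq(-grid_half, grid_half, by = grid_step)
  ks <- stats::dnorm(xs, 0, s)
  if (4 * s < grid_step) stopf("grid too coarse for spatial SD s = %g", s)
  ks <- ks / sum(ks)
  structure(list(spatial = ks, spatial_x = xs, temporal = kt,
                 temporal_t = tmid[seq_len(keep)], s = s, a = a, b = b,
                 dt = dt),
            class = "model_kernel")
}

# spatial stimulus-contrast profiles on the model grid
model_grid <- function(params) {
  xs <- seq(-params$grid_half, params$grid_half, by = params$grid_step)
  list(xs = xs, r2 = outer(xs^2, xs^2, "+"))
}

target_profile <- function(stimulus, grid) {
  stimulus$target_contrast * exp(-grid$r2 / (2 * stimulus$target_sigma^2))
}

background_profile <- function(stimulus, grid) {
  rr <- sqrt(grid$r2)
  rad <- stimulus$background_diameter / 2
  stimulus$background_contrast *
    ifelse(rr <= rad, 0.5 * (1 + cos(pi * rr / rad)), 0)
}

# contrast correction factor lambda(x) = C_TB / sqrt(C_B^2 + C_T^2), with
# C_TB the local rms contrast (x sqrt(2)) of the summed luminance patterns
# in a Gaussian window of SD s_e, evaluated analytically for two cosine
# patterns with locally constant amplitude:
#   C_TB^2 = C_T^2 + C_B^2 + 2 gamma(x) C_T C_B,
# where the phase-coherence factor gamma(x) = a(dtheta) cos(dphi(x)) carries
# the windowed average of the product of the carrier waves: dphi is their
# phase difference at x (both cosine-centered) and a(dtheta) =
# exp(-2 (2 pi f s_e sin(dtheta/2))^2) the window attenuation of the
# difference wave. Fully coherent (contrast adds linearly) for the in-phase
# 0-deg background; quadrature (lambda = 1) for dissimilar orientations.
lambda_field <- function(stimulus, params, grid) {
  n <- length(grid$xs)
  if (stimulus$target_contrast == 0 || stimulus$background_contrast == 0) {
    return(matrix(1, n, n))
  }
  ct <- target_profile(stimulus, grid)
  cb <- background_profile(stimulus, grid)
  den2 <- ct^2 + cb^2
  f <- stimulus$spatial_frequency
  tho <- stimulus$target_orientation * pi / 180
  bho <- stimulus$background_orientation * pi / 180
  dth <- wrap_orientation(stimulus$target_orientation -
                            stimulus$background_orientation) * pi / 180
  atten <- exp(-2 * (2 * pi * f * params$omega_e$s * sin(dth / 2))^2)
  X <- matrix(grid$xs, n, n); Y <- t(X)
  dphi <- 2 * pi * f * ((sin(tho) - sin(bho)) * X +
                          (cos(tho) - cos(bho)) * Y)
  gam <- atten * cos(dphi)
  lam <- sqrt(pmax(1 + 2 * gam * ct * cb / pmax(den2, 1e-24), 0))
  lam[den2 <= 1e-24] <- 1
  lam
}

#' Effective-contrast fields for one orientation channel
#'
#' The effective background contrast seen by a channel preferring
#' `theta_max` is `c_B^e(x, t) = C_B(x) exp(-(theta_B - theta_max)^2 /
#' (2 sigma^2)) w(t; D)` (orientation differences wrapped to the acute
#' angle), and likewise for the target. For target plus background the
#' contrasts combine in quadrature with a phase-dependent correction,
#' `c_TB^e = lambda(x) sqrt(c_B^e^2 + c_T^e^2)`, where `lambda` is the ratio
#' of the local rms contrast of the summed patterns to the quadrature sum;
#' for the in-phase 0-deg background this makes contrast add linearly at the
#' center.
#'
#' @param stimulus a [stimulus_spec()].
#' @param theta_max channel preferred orientation, degrees.
#' @param sigma orientation tuning SD of the pathway, degrees (`Inf` for
#'   untuned).
#' @param params a [norm_model_params()] (grid and window settings).
#' @param lambda optional precomputed [lambda] field (channel independent);
#'   computed when absent.
#' @return list of spatial fields `c_t`, `c_b`, `c_tb`, `lambda`, and
#'   `pulse_duration` (the shared temporal pulse `w(t; D)`).
#' @export
effective_contrast <- function(stimulus, theta_max, sigma,
                               params = norm_model_params(), lambda = NULL) {
  if (!(sigma > 0)) stopf("sigma must be positive")
  grid <- model_grid(params)
  kt <- orientation_factor(stimulus$target_orientation - theta_max, sigma)
  kb <- orientation_factor(stimulus$background_orientation - theta_max,
                           sigma)
  ct <- target_profile(stimulus, grid) * kt
  cb <- background_profile(stimulus, grid) * kb
  if (stimulus$target_contrast > 0 && stimulus$background_contrast > 0) {
    if (is.null(lambda)) lambda <- lambda_field(stimulus, params, grid)
    ctb <- lambda * sqrt(cb^2 + ct^2)
  } else {
    lambda <- matrix(1, length(grid$xs), length(grid$xs))
    ctb <- cb + ct  # one of the two is zero everywhere
  }
  list(c_t = ct, c_b = cb, c_tb = ctb, lambda = lambda,
       pulse_duration = stimulus$duration)
}

#' Spatiotemporal drive of one channel
#'
#' Convolves a (separable) effective-contrast signal `C(x) w(t; D)` with the
#' channel's impulse response and evaluates at the stimulus center `x0`:
#' spatial pooling of `C(x)` by the unit-mass Gaussian kernel centered at
#' `x0`, times the causal convolution of the pulse with the unit-mass
#' temporal kernel. A spatially uniform field of contrast C therefore drives
#' asymptotically to C during a long pulse.
#'
#' @param field spatial contrast field on the model grid.
#' @param kernel a [impulse_kernel()].
#' @param params a [norm_model_params()].
#' @param pulse_duration D in ms.
#' @param x0 stimulus-center coordinates in degrees `c(x, y)`.
#' @return numeric drive time series on the fine time grid (`dt` steps from
#'   `dt` to `t_max`).
#' @export
channel_drive <- function(field, kernel, params, pulse_duration,
                          x0 = c(0, 0)) {
  xs <- kernel$spatial_x
  if (!all(dim(field) == length(xs))) {
    stopf("field is not on the kernel's spatial grid")
  }
  gx <- stats::dnorm(xs, x0[1], kernel$s)
  gy <- stats::dnorm(xs, x0[2], kernel$s)
  gx <- gx / sum(gx); gy <- gy / sum(gy)
  pooled <- as.numeric(t(gx) %*% field %*% gy)
  tt <- seq(params$dt, params$t_max, by = params$dt)
  w <- as.numeric(tt > 0 & tt <= pulse_duration)
  drive <- stats::convolve(w, rev(kernel$temporal),
                           type = "open")[seq_along(w)]
  pooled * drive
}

#' Divisive normalization of the drive signals
#'
#' `r(t) = r_e(t)^p / (r_n(t)^p + r0^p)`, pointwise; `r0 > 0` keeps the
#' response finite when the normalization signal vanishes.
#'
#' @param r_e,r_n excitation and normalization drive series.
#' @param params a [norm_model_params()].
#' @return response series.
#' @export
normalize_response <- function(r_e, r_n, params = norm_model_params()) {
  if (length(r_e) != length(r_n)) stopf("series lengths differ")
  r_e^params$p / (r_n^params$p + params$r0^params$p)
}

#' Simulate the 12-channel population response to a stimulus
#'
#' Runs the full model: per channel, effective-contrast fields for the
#' excitation and normalization pathways (each with its own orientation
#' tuning, spatial pooling and temporal kernel), spatiotemporal convolution
#' at the stimulus center, divisive normalization, and the response
#' exponent. All responses are divided by the reference response — the 24%
#' contrast target-only response of the target's channel averaged over
#' 50-200 ms — so model output is in reference-normalized units. Fine-step
#' output is box-averaged into `frame_ms` frames stamped at the end of each
#' bin, mirroring the imaging frame rate.
#'
#' @param stimulus a [stimulus_spec()].
#' @param params a [norm_model_params()].
#' @param keep_fine also retain the fine-time-step response.
#' @return an object of class `model_response`: `r` (frames x 12 matrix),
#'   `times` (frame stamps, ms), `channels`, components `r_e`, `r_n`
#'   (frames x 12), `reference_scale`, and optionally `r_fine`.
#' @export
simulate_population <- function(stimulus, params = norm_model_params(),
                                keep_fine = FALSE) {
  grid <- NULL
  ke <- impulse_kernel(params$omega_e$s, params$omega_e$a, params$omega_e$b,
                       params$dt, params$grid_step, params$grid_half)
  kn <- impulse_kernel(params$omega_n$s, params$omega_n$a, params$omega_n$b,
                       params$dt, params$grid_step, params$grid_half)
  lam <- if (stimulus$target_contrast > 0 &&
               stimulus$background_contrast > 0) {
    lambda_field(stimulus, params, model_grid(params))
  } else NULL

  nt <- length(seq(params$dt, params$t_max, by = params$dt))
  nch <- length(params$channels)
  re_m <- rn_m <- r_m <- matrix(0, nt, nch)
  for (j in seq_len(nch)) {
    th <- params$channels[j]
    ece <- effective_contrast(stimulus, th, params$omega_e$sigma, params,
                              lambda = lam)
    ecn <- effective_contrast(stimulus, th, params$omega_n$sigma, params,
                              lambda = lam)
    fe <- drive_input_field(stimulus, ece)
    fn <- drive_input_field(stimulus, ecn)
    re_m[, j] <- channel_drive(fe, ke, params, stimulus$duration)
    rn_m[, j] <- channel_drive(fn, kn, params, stimulus$duration)
    r_m[, j] <- normalize_response(re_m[, j], rn_m[, j], params)
  }

  ref <- reference_response(params)
  r_m <- r_m / ref

  frames <- frame_average(r_m, params)
  structure(list(r = frames$values, times = frames$times,
                 channels = params$channels,
                 r_e = frame_average(re_m, params)$values,
                 r_n = frame_average(rn_m, params)$values,
                 reference_scale = ref, stimulus = stimulus, params = params,
                 r_fine = if (keep_fine) r_m / 1 else NULL),
            class = "model_response")
}

# which effective-contrast field feeds the pathway for this stimulus class
drive_input_field <- function(stimulus, ec) {
  if (stimulus$target_contrast > 0 && stimulus$background_contrast > 0) {
    ec$c_tb
  } else if (stimulus$target_contrast > 0) {
    ec$c_t
  } else {
    ec$c_b
  }
}

# reference: 24% target-only response at the target's channel, mean 50-200 ms
reference_response <- function(params) {
  stim <- stimulus_spec(target_contrast = 0.24, duration = 250)
  ke <- impulse_kernel(params$omega_e$s, params$omega_e$a, params$omega_e$b,
                       params$dt, params$grid_step, params$grid_half)
  kn <- impulse_kernel(params$omega_n$s, params$omega_n$a, params$omega_n$b,
                       params$dt, params$grid_step, params$grid_half)
  ece <- effective_contrast(stim, stim$target_orientation,
                            params$omega_e$sigma, params)
  ecn <- effective_contrast(stim, stim$target_orientation,
                            params$omega_n$sigma, params)
  re <- channel_drive(ece$c_t, ke, params, stim$duration)
  rn <- channel_drive(ecn$c_t, kn, params, stim$duration)
  r <- normalize_response(re, rn, params)
  tt <- seq(params$dt, params$t_max, by = params$dt)
  mean(r[tt >= 50 & tt <= 200])
}

frame_average <- function(mat, params) {
  per <- round(params$frame_ms / params$dt)
  nfr <- floor(nrow(mat) / per)
  idx <- rep(seq_len(nfr), each = per)
  vals <- apply(mat[seq_len(nfr * per), , drop = FALSE], 2, function(col) {
    tapply(col, idx, mean)
  })
  list(values = matrix(vals, nfr, ncol(mat)),
       times = seq_len(nfr) * params$frame_ms)
}

#' @export
print.model_response <- function(x, ...) {
  pk <- model_popvec_magnitude(x)
  cat(sprintf(
    "<model_response> %d frames x %d channels; popvec magnitude peaks at %g ms\n",
    nrow(x$r), ncol(x$r), x$times[which.max(pk)]))
  invisible(x)
}

#' Population-vector magnitude time course of a model response
#'
#' @param response a `model_response`.
#' @return numeric vector, `|sum_k r_k exp(2 i theta_k)|` per frame.
#' @export
model_popvec_magnitude <- function(response) {
  abs(response$r %*% exp(2i * response$channels * pi / 180))[, 1]
}

#' Simulate the model over a set of background orientations
#'
#' Convenience wrapper producing, for each background orientation, the
#' background-only and target-plus-background responses, plus the target-only
#' response — the full stimulus set of a masking experiment.
#'
#' @param background_orientations degrees.
#' @param target_contrast,background_contrast Michelson fractions (24% target
#'   on 12% background by default).
#' @param params a [norm_model_params()].
#' @param duration stimulus duration, ms.
#' @return list with elements `tb` (list of `model_response` per
#'   orientation), `b` (likewise), `target_only`, and
#'   `background_orientations`.
#' @export
simulate_model_set <- function(background_orientations = c(0, 15, 30, 45,
                                                           60, 90),
                               target_contrast = 0.24,
                               background_contrast = 0.12,
                               params = norm_model_params(),
                               duration = 250) {
  b <- lapply(background_orientations, function(o) {
    simulate_population(stimulus_spec(background_contrast =
                                        background_contrast,
                                      background_orientation = o,
                                      duration = duration), params)
  })
  tb <- lapply(background_orientations, function(o) {
    simulate_population(stimulus_spec(target_contrast = target_contrast,
                                      background_contrast =
                                        background_contrast,
                                      background_orientation = o,
                                      duration = duration), params)
  })
  t_only <- simulate_population(stimulus_spec(target_contrast =
                                                target_contrast,
                                              duration = duration), params)
  list(tb = tb, b = b, target_only = t_only,
       background_orientations = background_orientations)
}

#' Frame-by-frame correlation between model response and behavior
#'
#' For every output frame, correlates the 0-90 readout of the target-evoked
#' model response (`TB - B`) across background orientations with a
#' behavioral sensitivity profile, using the trial-count-weighted
#' correlation. The default readout is the response of the channel tuned to
#' the target; `"popvec"` uses the real part of the population vector
#' instead.
#'
#' @param model_set a [simulate_model_set()] result.
#' @param behavior per-orientation behavioral d-prime (same order as the
#'   model set's orientations).
#' @param weights trial-count weights (equal by default).
#' @param readout `"channel"` or `"popvec"`.
#' @return data.frame with columns `t_ms`, `rho`, `p_value`, `n_eff`.
#' @export
model_behavior_correlation <- function(model_set, behavior, weights = NULL,
                                       readout = c("channel", "popvec")) {
  readout <- match.arg(readout)
  orient <- model_set$background_orientations
  if (length(behavior) != length(orient)) {
    stopf("one behavioral value per background orientation")
  }
  if (is.null(weights)) weights <- rep(1, length(orient))
  ch <- model_set$tb[[1]]$channels
  proj <- function(mr_tb, mr_b) {
    te <- mr_tb$r - mr_b$r
    if (readout == "channel") {
      te[, which.min(abs(wrap_orientation(
        ch - mr_tb$stimulus$target_orientation)))]
    } else {
      Re(te %*% exp(2i * ch * pi / 180))[, 1]
    }
  }
  mat <- mapply(proj, model_set$tb, model_set$b)  # frames x orientations
  times <- model_set$tb[[1]]$times
  rows <- lapply(seq_along(times), function(i) {
    wc <- weighted_correlation(mat[i, ], behavior, weights)
    data.frame(t_ms = times[i], rho = wc$rho, p_value = wc$p_value,
               n_eff = wc$n_eff)
  })
  do.call(rbind, rows)
}
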