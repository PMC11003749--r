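#' Stimulus specification
#'
#' Parameters of one detection-task stimulus: an additive horizontal Gabor
#' target (Michelson contrast `target_contrast`, Gaussian envelope sigma
#' `target_sigma` in degrees, 0.33 deg FWHM at the default 0.14 deg) over a
#' raised-cosine-windowed grating background of the same spatial frequency.
#' Both patterns are cosine-centered, so a 0 deg background is fully in phase
#' with the target. Orientations are in degrees with 0 = target (horizontal)
#' and are interpreted modulo 180.
#'
#' @param target_contrast,background_contrast Michelson fractions in `[0, 1]`.
#' @param target_orientation,background_orientation degrees.
#' @param target_sigma Gaussian envelope sigma, degrees of visual angle.
#' @param spatial_frequency cycles per degree.
#' @param background_diameter raised-cosine window diameter, degrees.
#' @param duration stimulus duration in ms.
#' @param phase_alignment logical; both patterns cosine-centered.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(target_contrast = 0, target_orientation = 0,
                          target_sigma = 0.14, spatial_frequency = 4,
                          background_contrast = 0, background_orientation = 0,
                          background_diameter = 4, duration = 250,
                          phase_alignment = TRUE) {
  if (target_contrast < 0 || target_contrast > 1 ||
      background_contrast < 0 || background_contrast > 1) {
    stopf("contrasts must lie in [0, 1]")
  }
  if (duration <= 0) stopf("duration must be positive")
  if (target_sigma <= 0) stopf("target_sigma must be positive")
  structure(
    list(target_contrast = target_contrast,
         target_orientation = wrap_orientation(target_orientation),
         target_sigma = target_sigma,
         spatial_frequency = spatial_frequency,
         background_contrast = background_contrast,
         background_orientation = wrap_orientation(background_orientation),
         background_diameter = background_diameter,
         duration = duration,
         phase_alignment = isTRUE(phase_alignment)),
    class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> target C=%.3g at %g deg; background C=%.3g at %g deg; D=%g ms\n",
    x$target_contrast, x$target_orientation, x$background_contrast,
    x$background_orientation, x$duration))
  invisible(x)
}

#' Generate ground-truth cortical maps
#'
#' Builds the generative maps a synthetic session is rendered from: a 2D
#' Gaussian retinotopic response envelope (the cortical point image of the
#' target) and a columnar orientation map. The orientation map is the
#' angle-halved argument of a random complex field whose spatial spectrum is
#' strictly confined to `column_band` (cycles/mm), so the columnar component
#' `A exp(2i theta)` of any noiseless render is band-limited by construction.
#' The columnar magnitude `A` is normalized to unit mean.
#'
#' @param grid_shape pixel dimensions, e.g. `c(128, 128)`.
#' @param mm_per_pixel pixel pitch in mm (default 8 mm field over 128 px).
#' @param envelope_center pixel coordinates (row, col) of the envelope peak;
#'   defaults to the grid center.
#' @param envelope_sigma_mm envelope sigma in mm.
#' @param column_band low/high spatial-frequency cutoffs in cycles/mm.
#' @param seed integer; the maps are a pure function of the arguments.
#' @return an object of class `vsd_maps` with fields `envelope`, `theta`
#'   (preferred orientation per pixel, degrees in `[0, 180)`), `A` (columnar
#'   magnitude), and geometry metadata.
#' @export
make_ground_truth <- function(grid_shape = c(128, 128), mm_per_pixel = 8 / 128,
                              envelope_center = NULL, envelope_sigma_mm = 1.0,
                              column_band = c(0.8, 3.0), seed = 1) {
  if (envelope_sigma_mm <= 0) stopf("envelope_sigma_mm must be positive")
  if (column_band[1] >= column_band[2]) stopf("column_band low must be < high")
  nyq <- 1 / (2 * mm_per_pixel)
  if (column_band[2] > nyq) {
    stopf("column_band upper edge %.3g cycles/mm exceeds Nyquist %.3g for mm_per_pixel = %.4g",
          column_band[2], nyq, mm_per_pixel)
  }
  h <- grid_shape[1]; w <- grid_shape[2]
  if (is.null(envelope_center)) envelope_center <- c((h + 1) / 2, (w + 1) / 2)

  z <- with_seed(seed, {
    re <- matrix(stats::rnorm(h * w), h, w)
    im <- matrix(stats::rnorm(h * w), h, w)
    re + 1i * im
  })
  fr <- fft_freq(h, mm_per_pixel)
  fc <- fft_freq(w, mm_per_pixel)
  rho <- sqrt(outer(fr^2, fc^2, "+"))
  mask <- rho >= column_band[1] & rho <= column_band[2]
  zf <- stats::fft(z) * mask
  field <- stats::fft(zf, inverse = TRUE) / (h * w)

  A <- Mod(field)
  A <- A / mean(A)
  theta <- (Arg(field) / 2 * 180 / pi) %% 180

  rows <- (seq_len(h) - envelope_center[1]) * mm_per_pixel
  cols <- (seq_len(w) - envelope_center[2]) * mm_per_pixel
  envelope <- exp(-outer(rows^2, cols^2, "+") / (2 * envelope_sigma_mm^2))

  structure(
    list(envelope = envelope, theta = theta, A = A,
         mm_per_pixel = mm_per_pixel, grid_shape = c(h, w),
         envelope_center = envelope_center,
         envelope_sigma_mm = envelope_sigma_mm,
         column_band = column_band, seed = seed),
    class = "vsd_maps")
}

#' @export
print.vsd_maps <- function(x, ...) {
  cat(sprintf(
    "<vsd_maps> %dx%d px @ %.4g mm/px; envelope sigma %.3g mm; columns %.2g-%.2g cycles/mm\n",
    x$grid_shape[1], x$grid_shape[2], x$mm_per_pixel, x$envelope_sigma_mm,
    x$column_band[1], x$column_band[2]))
  invisible(x)
}

#' Noise specification for synthetic renders
#'
#' VSDI noise is modeled as the sum of white per-pixel noise and a spatially
#' correlated component (Gaussian-filtered white field, renormalized to unit
#' pixel SD before scaling), both in dF/F units, plus an optional global
#' heartbeat-locked sinusoid. The defaults give single-trial decoding a
#' realistic signal-to-noise ratio for a well-stained VSD preparation.
#'
#' @param white_sd per-pixel, per-frame SD of the white component (dF/F).
#' @param corr_sd per-pixel SD of the correlated component (dF/F).
#' @param corr_length_mm Gaussian correlation length of the slow component.
#' @param heartbeat_amp amplitude of a global ~2 Hz sinusoid (dF/F).
#' @param heartbeat_freq heartbeat frequency, Hz.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 2e-3, corr_sd = 1e-3, corr_length_mm = 0.5,
                       heartbeat_amp = 0, heartbeat_freq = 2) {
  if (white_sd < 0 || corr_sd < 0 || heartbeat_amp < 0) {
    stopf("noise amplitudes must be non-negative")
  }
  structure(list(white_sd = white_sd, corr_sd = corr_sd,
                 corr_length_mm = corr_length_mm,
                 heartbeat_amp = heartbeat_amp,
                 heartbeat_freq = heartbeat_freq),
            class = "noise_spec")
}

#' Motion specification for synthetic renders
#'
#' Slow camera/cortex translation injected through the separable motion model
#' `I(x, t) = I0(x, t) + alpha(x) . v(t)`, with the coupling field `alpha`
#' taken as the spatial gradient of the baseline fluorescence pattern (the
#' first-order effect of a true sub-pixel translation). `v(t)` is a sinusoid
#' of the given amplitude (pixels) along `direction_deg`.
#'
#' @param amplitude_px peak translation in pixels (0 disables motion).
#' @param frequency_hz temporal frequency of the sinusoid.
#' @param direction_deg direction of motion in the image plane.
#' @param phase phase offset in radians.
#' @return an object of class `motion_spec`.
#' @export
motion_spec <- function(amplitude_px = 0, frequency_hz = 1,
                        direction_deg = 30, phase = 0) {
  structure(list(amplitude_px = amplitude_px, frequency_hz = frequency_hz,
                 direction_deg = direction_deg, phase = phase),
            class = "motion_spec")
}

# gamma-kernel temporal response profile: stimulus on/off trace convolved with
# a latency-shifted gamma density, normalized to unit peak so that the peak
# dF/F of a rendered response equals response_gain * contrast exactly.
response_profile <- function(stim_on, frame_rate, latency_ms = 40,
                             shape = 3, scale_ms = 20) {
  dt <- 1000 / frame_rate
  tk <- seq(dt / 2, 600, by = dt)
  k <- stats::dgamma(tk - latency_ms, shape = shape, scale = scale_ms) * dt
  if (sum(k) == 0) return(rep(0, length(stim_on)))
  prof <- stats::convolve(stim_on, rev(k), type = "open")[seq_along(stim_on)]
  m <- max(prof)
  if (m > 0) prof <- prof / m
  prof
}

# on/off indicator for a stimulus: single pulse, or a 5 Hz flash train
stimulus_on_trace <- function(n_frames, onset_index, frame_rate, duration,
                              flash = NULL) {
  tt <- (seq_len(n_frames) - onset_index) * 1000 / frame_rate
  if (is.null(flash)) {
    as.numeric(tt >= 0 & tt < duration)
  } else {
    period <- 1000 / flash$rate
    ph <- tt %% period
    as.numeric(tt >= 0 & tt < flash$train_ms & ph < flash$on_ms)
  }
}

# default baseline fluorescence pattern: bright with smooth mottle, strictly
# positive, deterministic given seed
baseline_pattern <- function(grid_shape, seed) {
  h <- grid_shape[1]; w <- grid_shape[2]
  raw <- with_seed(seed, matrix(stats::rnorm(h * w), h, w))
  sm <- gauss_smooth_fft(raw, sigma_px = max(2, round(min(h, w) / 16)))
  sm <- sm / stats::sd(sm)
  100 * (1 + 0.15 * sm)
}

# central-difference spatial gradient of a matrix, rows then cols
spatial_gradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gr <- (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
  gc <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
  list(row = gr, col = gc)
}

#' Render one synthetic VSDI trial stack
#'
#' Produces a raw-fluorescence stack for a stimulus over ground-truth maps.
#' The noiseless dF/F signal is
#' `gain * profile(t) * [C_T env(x) (1 + m A cos 2(theta - theta_T)) +
#'  C_B (1 + m A cos 2(theta - theta_B))]`,
#' i.e. a retinotopic envelope response to the target, a spatially uniform
#' background response, and columnar modulation with depth `columnar_depth`
#' riding on each. The temporal profile is a gamma-kernel rise (latency
#' ~40 ms, unit peak). Noise (dF/F units) and additive motion
#' `alpha(x) . v(t)` are then applied on top of a multiplicative baseline
#' pattern F0(x).
#'
#' @param stimulus a [stimulus_spec()]; set a contrast to 0 for
#'   background-only / target-only variants.
#' @param maps a [make_ground_truth()] result.
#' @param response_gain peak dF/F per unit Michelson contrast.
#' @param columnar_depth relative depth of columnar modulation.
#' @param noise a [noise_spec()] (use `noise_spec(0, 0)` for noiseless).
#' @param motion a [motion_spec()] or `NULL`.
#' @param seed integer; the render is a pure function of its arguments.
#' @param n_frames,frame_rate,onset_index stack geometry (1.2 s trials at
#'   100 Hz with onset at frame 21 by default).
#' @param flash optional flash-train spec `list(rate, on_ms, train_ms)` for
#'   fixation-block renders (5 Hz, 60 ms ON, 1.0 s train by default usage).
#' @param baseline optional baseline fluorescence matrix F0(x).
#' @return a raw-fluorescence `vsd_stack`.
#' @export
render_trial_stack <- function(stimulus, maps, response_gain = 0.01,
                               columnar_depth = 0.15,
                               noise = noise_spec(), motion = NULL,
                               seed = 1, n_frames = 120, frame_rate = 100,
                               onset_index = 21, flash = NULL,
                               baseline = NULL) {
  h <- maps$grid_shape[1]; w <- maps$grid_shape[2]
  theta_r <- maps$theta * pi / 180
  spatial <- 0
  if (stimulus$target_contrast > 0) {
    colmod_t <- 1 + columnar_depth * maps$A *
      cos(2 * (theta_r - stimulus$target_orientation * pi / 180))
    spatial <- spatial + stimulus$target_contrast * maps$envelope * colmod_t
  }
  if (stimulus$background_contrast > 0) {
    colmod_b <- 1 + columnar_depth * maps$A *
      cos(2 * (theta_r - stimulus$background_orientation * pi / 180))
    spatial <- spatial + stimulus$background_contrast * colmod_b
  }
  if (identical(spatial, 0)) spatial <- matrix(0, h, w)

  stim_on <- stimulus_on_trace(n_frames, onset_index, frame_rate,
                               stimulus$duration, flash)
  prof <- response_profile(stim_on, frame_rate)

  if (is.null(baseline)) baseline <- baseline_pattern(maps$grid_shape, maps$seed)

  dff <- array(0, c(h, w, n_frames))
  sig <- response_gain * spatial
  for (t in seq_len(n_frames)) dff[, , t] <- sig * prof[t]

  if (noise$white_sd > 0 || noise$corr_sd > 0 || noise$heartbeat_amp > 0) {
    corr_sigma_px <- noise$corr_length_mm / maps$mm_per_pixel
    hb_phase <- 0
    with_seed(seed, {
      if (noise$heartbeat_amp > 0) hb_phase <- stats::runif(1, 0, 2 * pi)
      tt <- (seq_len(n_frames) - onset_index) / frame_rate
      for (t in seq_len(n_frames)) {
        fr <- 0
        if (noise$white_sd > 0) {
          fr <- fr + noise$white_sd * matrix(stats::rnorm(h * w), h, w)
        }
        if (noise$corr_sd > 0) {
          sm <- gauss_smooth_fft(matrix(stats::rnorm(h * w), h, w),
                                 corr_sigma_px)
          fr <- fr + noise$corr_sd * sm / stats::sd(sm)
        }
        if (noise$heartbeat_amp > 0) {
          fr <- fr + noise$heartbeat_amp *
            sin(2 * pi * noise$heartbeat_freq * tt[t] + hb_phase)
        }
        dff[, , t] <- dff[, , t] + fr
      }
    })
  }

  frames <- array(0, c(h, w, n_frames))
  for (t in seq_len(n_frames)) frames[, , t] <- baseline * (1 + dff[, , t])

  if (!is.null(motion) && motion$amplitude_px > 0) {
    g <- spatial_gradient(baseline)
    tt <- (seq_len(n_frames) - onset_index) / frame_rate
    vt <- motion$amplitude_px *
      sin(2 * pi * motion$frequency_hz * tt + motion$phase)
    dirr <- c(cos(motion$direction_deg * pi / 180),
              sin(motion$direction_deg * pi / 180))
    for (t in seq_len(n_frames)) {
      frames[, , t] <- frames[, , t] +
        (g$row * dirr[1] + g$col * dirr[2]) * vt[t]
    }
  }

  image_stack(frames, frame_rate = frame_rate, onset_index = onset_index,
              is_dff = FALSE, mm_per_pixel = maps$mm_per_pixel)
}

#' Simulate behavioral outcomes of an equal-variance Gaussian observer
#'
#' Inverse of the d-prime model used for analysis: on target-present trials
#' the observer reports "present" with probability `Phi(dprime/2 - criterion)`
#' (a hit), on target-absent trials with probability
#' `Phi(-dprime/2 - criterion)` (a false alarm). Reaction times are drawn only
#' for saccade outcomes (hits, false alarms) from a 75 ms-shifted log-normal,
#' floored at the 75 ms minimum allowed reaction time.
#'
#' @param dprime,criterion observer sensitivity and bias.
#' @param target_present logical vector; one trial per entry.
#' @param rt_params list with `shift` (ms), `meanlog`, `sdlog` of the
#'   log-normal reaction-time generator.
#' @param seed integer seed.
#' @return data.frame with columns `target_present`, `outcome`
#'   (hit/miss/correct_reject/false_alarm) and `rt_ms` (`NA` for non-saccade
#'   outcomes).
#' @export
simulate_behavior_outcome <- function(dprime, criterion, target_present,
                                      rt_params = list(shift = 75,
                                                       meanlog = log(120),
                                                       sdlog = 0.25),
                                      seed = 1) {
  stopifnot(is.finite(dprime), is.finite(criterion))
  n <- length(target_present)
  p_yes <- ifelse(target_present,
                  stats::pnorm(dprime / 2 - criterion),
                  stats::pnorm(-dprime / 2 - criterion))
  with_seed(seed, {
    yes <- stats::runif(n) < p_yes
    outcome <- ifelse(target_present,
                      ifelse(yes, "hit", "miss"),
                      ifelse(yes, "false_alarm", "correct_reject"))
    rt <- rep(NA_real_, n)
    sac <- which(yes)
    if (length(sac)) {
      rt[sac] <- pmax(75, rt_params$shift +
                        stats::rlnorm(length(sac), rt_params$meanlog,
                                      rt_params$sdlog))
    }
    data.frame(target_present = target_present, outcome = outcome,
               rt_ms = rt, stringsAsFactors = FALSE)
  })
}

#' Session design
#'
#' Trial-count and stimulus bookkeeping for a synthetic experiment day:
#' a Fixation block (5 Hz flashed target, and flashed full-field gratings at
#' each map orientation, for template estimation), a Detection block
#' (backgrounds at the listed orientations, 50% target-present), and a
#' reference block of target-only detection trials on gray at several
#' contrasts (used for cross-experiment pooling).
#'
#' @param target_contrast,background_contrast Michelson fractions.
#' @param orientations background orientations, degrees.
#' @param trials_per_orientation detection trials per background orientation
#'   (half target-present).
#' @param map_orientations grating orientations for the fixation block.
#' @param fixation_reps flash-train trials per fixation stimulus.
#' @param reference_contrasts,reference_trials target-only reference block.
#' @param flash flash-train parameters (5 Hz, 60 ms ON, 1.0 s).
#' @return an object of class `session_design`.
#' @export
session_design <- function(target_contrast = 0.24, background_contrast = 0.12,
                           orientations = c(0, -15, 15, -30, 30, -45, 45,
                                            -60, 60, 90),
                           trials_per_orientation = 4,
                           map_orientations = seq(-75, 90, by = 15),
                           fixation_reps = 1,
                           reference_contrasts = c(0.06, 0.12, 0.24),
                           reference_trials = 3,
                           flash = list(rate = 5, on_ms = 60,
                                        train_ms = 1000)) {
  if (trials_per_orientation < 1) stopf("trials_per_orientation must be >= 1")
  structure(
    list(target_contrast = target_contrast,
         background_contrast = background_contrast,
         orientations = orientations,
         trials_per_orientation = trials_per_orientation,
         map_orientations = map_orientations,
         fixation_reps = fixation_reps,
         reference_contrasts = reference_contrasts,
         reference_trials = reference_trials,
         flash = flash),
    class = "session_design")
}

#' Simulate a complete synthetic VSDI session
#'
#' Generates the fixation, detection, and reference blocks of one experiment
#' day over ground-truth maps. Behavioral outcomes are drawn from the
#' equal-variance Gaussian observer with a d-prime profile following the
#' inverted-Gaussian masking law `d'(theta) = c - A exp(-theta^2 / (2
#' sigma^2))` across background orientation. All randomness derives from
#' `seed`.
#'
#' @param design a [session_design()].
#' @param maps a [make_ground_truth()] result.
#' @param masking_profile named vector `c(A=, sigma=, c=)` of the d-prime
#'   masking law.
#' @param criterion observer bias.
#' @param noise,motion specs passed to [render_trial_stack()].
#' @param response_gain,columnar_depth render parameters.
#' @param seed integer master seed.
#' @param render_images if `FALSE`, only the trial log and behavioral
#'   outcomes are generated (no image stacks).
#' @return an object of class `vsd_session`: `trials` (the trial log),
#'   `stacks` (list, parallel to rows of `trials`, or `NULL`),
#'   `ground_truth`, `design`, `seed`.
#' @export
simulate_session <- function(design = session_design(), maps,
                             masking_profile = c(A = 1.5, sigma = 30, c = 2.5),
                             criterion = 0.5,
                             noise = noise_spec(), motion = NULL,
                             response_gain = 0.01, columnar_depth = 0.15,
                             seed = 1, render_images = TRUE) {
  rows <- list()
  add_row <- function(block, stim_kind, ct, tori, cb, bori, target_present,
                      outcome = NA_character_, rt = NA_real_, flash = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      block = block, stim_kind = stim_kind, target_contrast = ct,
      target_orientation = tori, background_contrast = cb,
      background_orientation = bori, target_present = target_present,
      outcome = outcome, rt_ms = rt, flashed = flash,
      stringsAsFactors = FALSE)
  }

  # fixation block: flashed target, then flashed gratings
  for (r in seq_len(design$fixation_reps)) {
    add_row("fixation", "target_flash", design$target_contrast, 0, 0, NA,
            FALSE, flash = TRUE)
    for (o in design$map_orientations) {
      add_row("fixation", "grating_flash", 0, NA, 1.0, o, FALSE, flash = TRUE)
    }
  }

  # detection block: balanced target-present within each orientation
  A <- masking_profile[["A"]]; sg <- masking_profile[["sigma"]]
  cc <- masking_profile[["c"]]
  for (o in design$orientations) {
    pres <- rep(c(TRUE, FALSE), length.out = design$trials_per_orientation)
    for (p in pres) {
      add_row("detection", "detection", design$target_contrast, 0,
              design$background_contrast, o, p)
    }
  }

  # reference block: target-only detection on gray, 50% target present
  for (ct in design$reference_contrasts) {
    pres <- rep(c(TRUE, FALSE), length.out = design$reference_trials)
    for (p in pres) {
      add_row("reference", "reference", ct, 0, 0, NA, p)
    }
  }

  trials <- do.call(rbind, rows)
  trials$trial_id <- seq_len(nrow(trials))
  seeds <- derive_seeds(seed, nrow(trials) + 1)

  # behavioral outcomes: masking-law d' in the detection block; on gray the
  # baseline d' is the masking asymptote c, scaled linearly with target
  # contrast for the reference contrast series
  beh <- which(trials$block %in% c("detection", "reference"))
  dpr <- ifelse(trials$block[beh] == "detection",
                cc - A * exp(-trials$background_orientation[beh]^2 /
                               (2 * sg^2)),
                cc * trials$target_contrast[beh] / design$target_contrast)
  for (i in seq_along(beh)) {
    b <- simulate_behavior_outcome(dpr[i], criterion,
                                   trials$target_present[beh[i]],
                                   seed = seeds[trials$trial_id[beh[i]]])
    trials$outcome[beh[i]] <- b$outcome
    trials$rt_ms[beh[i]] <- b$rt_ms
  }

  stacks <- NULL
  if (render_images) {
    stacks <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      stim <- stimulus_spec(
        target_contrast = if (isTRUE(tr$target_present) ||
                              tr$stim_kind %in% c("target_flash")) {
          tr$target_contrast
        } else 0,
        target_orientation = ifelse(is.na(tr$target_orientation), 0,
                                    tr$target_orientation),
        background_contrast = tr$background_contrast,
        background_orientation = ifelse(is.na(tr$background_orientation), 0,
                                        tr$background_orientation))
      stacks[[i]] <- render_trial_stack(
        stim, maps, response_gain = response_gain,
        columnar_depth = columnar_depth, noise = noise, motion = motion,
        seed = seeds[i],
        flash = if (tr$flashed) design$flash else NULL)
    }
  }

  structure(list(trials = trials, stacks = stacks, ground_truth = maps,
                 design = design, masking_profile = masking_profile,
                 criterion = criterion, seed = seed,
                 render_params = list(response_gain = response_gain,
                                      columnar_depth = columnar_depth,
                                      noise = noise, motion = motion)),
            class = "vsd_session")
}

#' @export
print.vsd_session <- function(x, ...) {
  tab <- table(x$trials$block)
  cat(sprintf("<vsd_session> seed %d; trials: %s; stacks %s\n", x$seed,
              paste(names(tab), tab, sep = "=", collapse = ", "),
              if (is.null(x$stacks)) "not rendered" else "rendered"))
  invisible(x)
}

#' Write / read a session trial log as CSV
#'
#' @param session a `vsd_session` (or its `trials` data.frame).
#' @param path CSV file path.
#' @return `read_trial_log` returns the trial-log data.frame.
#' @export
write_trial_log <- function(session, path) {
  trials <- if (inherits(session, "vsd_session")) session$trials else session
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
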