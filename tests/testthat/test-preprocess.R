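test_that("motion estimation returns zero on a static stack", {
  maps <- small_maps()
  st <- render_trial_stack(stimulus_spec(), maps, noise = noiseless(),
                           seed = 2, n_frames = 30)
  mo <- estimate_motion(st)
  expect_equal(max(abs(mo$v)), 0)
  expect_equal(max(abs(mo$alpha)), 0)
  expect_identical(stabilize(st, mo)$frames, st$frames)
})

test_that("planted sub-pixel motion is recovered and removed", {
  maps <- small_maps()
  st <- render_trial_stack(stimulus_spec(), maps, noise = noiseless(),
                           motion = motion_spec(amplitude_px = 0.5,
                                                frequency_hz = 1.3),
                           seed = 2, n_frames = 60)
  mo <- estimate_motion(st)
  tt <- (seq_len(60) - st$onset_index) / st$frame_rate
  v_true <- 0.5 * sin(2 * pi * 1.3 * tt)
  dirr <- c(cos(30 * pi / 180), sin(30 * pi / 180))
  vt <- cbind(v_true * dirr[1], v_true * dirr[2])
  err <- sweep(mo$v, 2, colMeans(mo$v)) - sweep(vt, 2, colMeans(vt))
  expect_lt(sqrt(mean(err^2)), 0.1)

  # >= 90% of temporal variance removed at strongly coupled pixels
  sb <- stabilize(st, mo)
  va <- apply(st$frames, c(1, 2), stats::var)
  vb <- apply(sb$frames, c(1, 2), stats::var)
  am <- sqrt(mo$alpha[, , 1]^2 + mo$alpha[, , 2]^2)
  hi <- am > stats::quantile(am, 0.9)
  expect_gt(1 - sum(vb[hi]) / sum(va[hi]), 0.9)

  # a second fit explains < 5% of the variance the first fit explained
  explained <- function(stack, motion) {
    vc <- sweep(motion$v, 2, colMeans(motion$v))
    tot <- 0
    for (t in seq_len(nrow(vc))) {
      tot <- tot + sum((motion$alpha[, , 1] * vc[t, 1] +
                          motion$alpha[, , 2] * vc[t, 2])^2)
    }
    tot
  }
  mo2 <- estimate_motion(sb)
  expect_lt(explained(sb, mo2), 0.05 * explained(st, mo))

  # stabilization is idempotent
  sb2 <- stabilize(sb, mo2)
  rel <- sqrt(mean((sb2$frames - sb$frames)^2)) /
    sqrt(mean((sb$frames - mean(sb$frames))^2))
  expect_lt(rel, 0.01)

  # metadata untouched
  expect_equal(sb$onset_index, st$onset_index)
  expect_equal(sb$frame_rate, st$frame_rate)
})

test_that("dF/F of a motion-free noiseless render is invariant under estimate+stabilize", {
  maps <- small_maps()
  st <- render_trial_stack(stimulus_spec(), maps, noise = noiseless(),
                           seed = 7, n_frames = 40)
  d0 <- delta_f_over_f(st)
  d1 <- delta_f_over_f(stabilize(st, estimate_motion(st)))
  expect_lt(max(abs(d0$frames - d1$frames)), 1e-10)
})

test_that("dF/F normalization matches its definition", {
  f0 <- matrix(100, 8, 8)
  frames <- array(100, c(8, 8, 30))
  st <- image_stack(frames, onset_index = 11)
  expect_equal(max(abs(delta_f_over_f(st)$frames)), 0)

  # 1% step strictly after the baseline window
  frames[, , 12:30] <- 101
  st <- image_stack(frames, onset_index = 11)
  d <- delta_f_over_f(st)
  expect_equal(d$frames[1, 1, 5], 0)
  expect_equal(d$frames[1, 1, 20], 0.01)
  expect_true(d$is_dff)

  # non-positive baseline is rejected with pixel diagnostics
  frames[3, 4, 1:10] <- -1000
  expect_error(delta_f_over_f(image_stack(frames, onset_index = 11)),
               "F0 <= 0")
})

test_that("closed loop: peak dF/F equals response_gain times contrast", {
  maps_c <- make_ground_truth(grid_shape = c(48, 48), mm_per_pixel = 8 / 48,
                              envelope_center = c(25, 25), seed = 5)
  g <- 0.013; ct <- 0.3
  st <- render_trial_stack(stimulus_spec(target_contrast = ct), maps_c,
                           response_gain = g, columnar_depth = 0,
                           noise = noiseless(), seed = 1)
  d <- delta_f_over_f(st)
  expect_lt(abs(max(d$frames[25, 25, ]) - g * ct), 1e-12)
})

test_that("columnar bandpass passes the band and rejects outside it", {
  mpp <- 8 / 64
  xs <- (1:64) * mpp
  expect_equal(max(abs(bandpass_columnar(matrix(3, 64, 64),
                                         mm_per_pixel = mpp))), 0)

  g_in <- outer(rep(1, 64), sin(2 * pi * 1.5 * xs))   # 1.5 cycles/mm
  out_in <- bandpass_columnar(g_in, mm_per_pixel = mpp)
  expect_gt(max(abs(out_in)), 0.95 * max(abs(g_in)))

  g_lo <- outer(rep(1, 64), sin(2 * pi * 0.25 * xs))  # 0.25 cycles/mm
  out_lo <- bandpass_columnar(g_lo, mm_per_pixel = mpp)
  expect_lt(max(abs(out_lo)), 0.05 * max(abs(g_lo)))

  # linear and idempotent on band-interior content, and mean-free
  # (2.25 cycles/mm is exactly periodic on the 8 mm field)
  f <- g_in + 0.5 * outer(sin(2 * pi * 2.25 * xs), rep(1, 64))
  b1 <- bandpass_columnar(f, mm_per_pixel = mpp)
  b2 <- bandpass_columnar(b1, mm_per_pixel = mpp)
  expect_lt(sqrt(mean((b2 - b1)^2)), 1e-10)
  expect_lt(abs(mean(b1)), 1e-12)
  lin <- bandpass_columnar(2 * f + g_lo, mm_per_pixel = mpp)
  expect_lt(max(abs(lin - (2 * b1 + out_lo))), 1e-10)
})

test_that("flash response extraction is a Fourier amplitude at the flash rate", {
  n <- 120
  tt <- (seq_len(n) - 21) / 100
  frames <- array(0, c(4, 4, n))
  a <- 0.037
  for (t in seq_len(n)) {
    frames[1, 1, t] <- a * sin(2 * pi * 5 * tt[t])
    frames[2, 2, t] <- 0.5
  }
  st <- image_stack(frames, onset_index = 21, is_dff = TRUE)
  fm <- extract_flash_response(st, 5)
  expect_equal(fm$amplitude[1, 1], a, tolerance = 1e-9)
  expect_equal(fm$amplitude[2, 2], 0, tolerance = 1e-9)

  # invariant to the flash's temporal phase
  for (t in seq_len(n)) {
    frames[1, 1, t] <- a * sin(2 * pi * 5 * tt[t] + 1.1)
  }
  fm2 <- extract_flash_response(image_stack(frames, onset_index = 21,
                                            is_dff = TRUE), 5)
  expect_equal(fm2$amplitude[1, 1], a, tolerance = 1e-9)

  # unresolvable frequency is rejected
  expect_error(extract_flash_response(st, 5, window = c(0, 150)),
               "resolve")
})

test_that("fixation-block flash amplitude recovers the retinotopic envelope", {
  maps <- small_maps()
  st <- render_trial_stack(stimulus_spec(target_contrast = 0.24), maps,
                           columnar_depth = 0, noise = noiseless(), seed = 1,
                           flash = flash_train())
  fm <- extract_flash_response(delta_f_over_f(st))
  expect_gt(stats::cor(as.vector(fm$amplitude), as.vector(maps$envelope)),
            0.95)
})

test_that("downsampling block-averages and rescales the pixel pitch", {
  frames <- array(seq_len(4 * 4 * 2), c(4, 4, 2))
  st <- image_stack(frames, onset_index = 1, mm_per_pixel = 0.1)
  dsub <- downsample_stack(st, 2)
  expect_equal(dim(dsub$frames), c(2, 2, 2))
  expect_equal(dsub$frames[1, 1, 1], mean(frames[1:2, 1:2, 1]))
  expect_equal(dsub$mm_per_pixel, 0.2)
  expect_error(downsample_stack(st, 3), "divide")
})
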