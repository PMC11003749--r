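render_gaussian_map <- function(h = 40, w = 40, center = c(18, 24),
                                sx = 5, sy = 3, rot = 0.4, amp = 2,
                                off = 0.3) {
  rr <- row(matrix(0, h, w)) - center[1]
  cc <- col(matrix(0, h, w)) - center[2]
  u <- (rr * cos(rot) + cc * sin(rot)) / sx
  v <- (-rr * sin(rot) + cc * cos(rot)) / sy
  off + amp * exp(-0.5 * (u^2 + v^2))
}

test_that("an exact Gaussian map is recovered to high precision", {
  m <- render_gaussian_map()
  fit <- fit_retinotopic_template(m, mm_per_pixel = 1)
  p <- fit$params
  expect_equal(p$center, c(18, 24), tolerance = 1e-6)
  expect_equal(p$sigma_major_px, 5, tolerance = 1e-6)
  expect_equal(p$sigma_minor_px, 3, tolerance = 1e-6)
  expect_equal(p$amplitude, 2, tolerance = 1e-6)
  expect_equal(p$offset, 0.3, tolerance = 1e-6)

  # adding a constant changes only the offset
  fit2 <- fit_retinotopic_template(m + 1.7, mm_per_pixel = 1)
  expect_equal(fit2$params$offset, 2.0, tolerance = 1e-6)
  expect_equal(fit2$params$sigma_major_px, 5, tolerance = 1e-5)
  expect_equal(fit2$params$center, c(18, 24), tolerance = 1e-5)

  expect_error(fit_retinotopic_template(matrix(1, 20, 20)), "flat")
})

test_that("template fit survives moderate noise on a synthetic fixation block", {
  # a fixation block holds several flash-train trials; average the dF/F
  # stacks coherently before amplitude extraction, as the estimation
  # protocol does (noise amplitude is positively biased per trial)
  maps <- make_ground_truth(seed = 23)  # full 128 px grid
  n_trials <- 16
  acc <- NULL
  for (k in seq_len(n_trials)) {
    st <- delta_f_over_f(render_trial_stack(
      stimulus_spec(target_contrast = 0.24), maps, columnar_depth = 0,
      noise = noise_spec(white_sd = 1e-3, corr_sd = 3e-4),
      seed = 300 + k, flash = flash_train()))
    acc <- if (is.null(acc)) st else {
      acc$frames <- acc$frames + st$frames; acc
    }
  }
  acc$frames <- acc$frames / n_trials
  fit <- fit_retinotopic_template(extract_flash_response(acc))
  expect_lt(max(abs(fit$params$center - maps$envelope_center)), 1)
  expect_lt(abs(fit$params$sigma_major_mm - 1.0), 0.05)
  expect_lt(abs(fit$params$sigma_minor_mm - 1.0), 0.05)
})

test_that("columnar map: single-orientation responders, rotation equivariance", {
  tpl <- small_templates()$template
  h <- nrow(tpl$h_ret)
  orients <- c(0, 45, 90, 135)
  # pixel (1,1) responds only to the 0-deg grating
  resp <- lapply(orients, function(o) matrix(0, h, h))
  resp[[1]][1, 1] <- 1
  cm <- fit_columnar_map(resp, orients, tpl, mm_per_pixel = 8 / 48,
                         bandpass = FALSE)
  expect_equal(cm$theta[1, 1], 0)

  # rotating every grating label by +30 rotates the recovered preferences
  maps <- small_maps()
  grats <- lapply(seq(0, 165, 22.5), function(o) {
    extract_flash_response(delta_f_over_f(render_trial_stack(
      stimulus_spec(background_contrast = 1, background_orientation = o),
      maps, noise = noiseless(), seed = 1, flash = flash_train())))
  })
  cm1 <- fit_columnar_map(grats, seq(0, 165, 22.5), tpl)
  cm2 <- fit_columnar_map(grats, seq(0, 165, 22.5) + 30, tpl)
  dd <- orientation_difference(cm2$theta[cm2$mask], cm1$theta[cm1$mask] + 30)
  expect_lt(max(abs(dd)), 1e-6)

  expect_error(fit_columnar_map(resp[1:2], orients[1:2], tpl,
                                mm_per_pixel = 8 / 48), "3")
})

test_that("noiseless closed loop recovers the ground-truth orientation map", {
  fx <- small_templates()
  cc <- vsdmask:::circular_orientation_cor(fx$cmap$theta[fx$cmap$mask],
                                           fx$maps$theta[fx$cmap$mask])
  expect_gt(cc, 0.99)
})

test_that("pixel variance maps estimate planted noise and scale correctly", {
  h <- 16
  mk <- function(sd, seed) {
    arr <- vsdmask:::with_seed(seed,
      array(stats::rnorm(h * h * 20, sd = sd), c(h, h, 20)))
    image_stack(arr, onset_index = 5, is_dff = TRUE, mm_per_pixel = 0.5)
  }
  stacks <- lapply(1:50, function(i) mk(0.2, i))
  vm <- estimate_pixel_variance(stacks, rep(1, 50), "retinotopic")
  expect_lt(abs(mean(vm$sigma2) - 0.04), 0.004)

  stacks2 <- lapply(1:50, function(i) mk(0.4, i))
  vm2 <- estimate_pixel_variance(stacks2, rep(1, 50), "retinotopic")
  expect_equal(mean(vm2$sigma2) / mean(vm$sigma2), 4, tolerance = 0.01)

  # identical trials give zero variance, then the floor applies
  same <- mk(0.1, 99)
  vm0 <- estimate_pixel_variance(list(same, same, stacks[[1]], stacks[[2]]),
                                 c("a", "a", "b", "b"), "retinotopic")
  expect_true(all(vm0$sigma2 >= vm0$floor))
  expect_error(estimate_pixel_variance(stacks[1:2], c("a", "b"),
                                       "retinotopic"), ">= 2")
})

test_that("retinotopic decoder is a normalized reliability-weighted projection", {
  tpl <- small_templates()$template
  h <- nrow(tpl$h_ret)
  arr <- array(0, c(h, h, 3))
  arr[, , 1] <- tpl$h_ret
  # a field orthogonal to the template
  orth <- matrix(stats::rnorm(h * h), h, h)
  orth <- orth - sum(orth * tpl$h_ret) / sum(tpl$h_ret^2) * tpl$h_ret
  arr[, , 2] <- orth
  arr[, , 3] <- tpl$h_ret + 3 * orth
  st <- image_stack(arr, onset_index = 1, is_dff = TRUE,
                    mm_per_pixel = 8 / 48)
  dec <- decode_retinotopic(st, tpl)
  expect_equal(dec$values[1], sqrt(sum(tpl$h_ret^2)), tolerance = 1e-10)
  expect_lt(abs(dec$values[2]), 1e-10)
  # orthogonal noise leaves the projection unchanged
  expect_equal(dec$values[3], dec$values[1], tolerance = 1e-10)
})

test_that("all decoders are linear in the input frame", {
  fx <- small_templates()
  d1 <- small_bg_dff(0)
  d2 <- small_bg_dff(45)
  dsum <- d1; dsum$frames <- d1$frames + d2$frames
  for (dec in list(
    function(s) decode_retinotopic(s, fx$template)$values,
    function(s) decode_columnar_axis(s, fx$cmap)$values,
    function(s) decode_population(s, fx$cmap)$values)) {
    expect_lt(max(abs(dec(dsum) - (dec(d1) + dec(d2))), na.rm = TRUE), 1e-10)
  }
})

test_that("columnar axis decoder sign convention and 45-deg null", {
  fx <- small_templates()
  win <- function(s) {
    v <- decode_columnar_axis(s, fx$cmap)$values
    mean(v[frames_in_window(s, c(50, 200))])
  }
  a0 <- win(small_bg_dff(0))
  a90 <- win(small_bg_dff(90))
  a45 <- win(small_bg_dff(45))
  am45 <- win(small_bg_dff(-45))
  expect_gt(a0, 0)
  expect_lt(a90, 0)
  expect_lt(abs(a45), 0.2 * abs(a0))
  expect_lt(abs(am45), 0.2 * abs(a0))
})

test_that("population decoder: tuning peaks, missing channels, balanced sum", {
  fx <- small_templates()
  pop0 <- decode_population(small_bg_dff(0), fx$cmap)
  win <- frames_in_window(small_bg_dff(0), c(50, 200))
  tun <- colMeans(pop0$values[win, ])
  expect_equal(fx$cmap$channels[which.max(tun)], 0)
  expect_equal(fx$cmap$channels[which.min(tun)], 90)

  # 45-deg grating peaks in the 45-deg bin
  pop45 <- decode_population(small_bg_dff(45), fx$cmap)
  tun45 <- colMeans(pop45$values[win, ])
  expect_equal(fx$cmap$channels[which.max(tun45)], 45)

  # channel sum vanishes for a zero-mean columnar-band field
  maps <- fx$maps
  f <- maps$A * cos(2 * (maps$theta - 30) * pi / 180)
  f <- f - mean(f)
  arr <- array(f, c(48, 48, 1))
  st <- image_stack(arr, onset_index = 1, is_dff = TRUE,
                    mm_per_pixel = 8 / 48)
  pv <- decode_population(st, fx$cmap, bandpassed = TRUE)$values[1, ]
  expect_lt(abs(sum(pv)), 0.15 * max(abs(pv)))

  # an empty orientation bin propagates as NA
  cmap2 <- fx$cmap
  cmap2$partitions[3] <- list(NULL)
  pop_na <- decode_population(small_bg_dff(0), cmap2)
  expect_true(all(is.na(pop_na$values[, 3])))
  expect_false(anyNA(pop_na$values[, 1]))
})

test_that("uniform variance maps reproduce unweighted projections", {
  fx <- small_templates()
  d <- small_bg_dff(15)
  vm <- structure(list(sigma2 = matrix(1, 48, 48), scale = "columnar",
                       floor = 1), class = "variance_maps")
  a1 <- decode_columnar_axis(d, fx$cmap)$values
  a2 <- decode_columnar_axis(d, fx$cmap, var = vm)$values
  expect_equal(a1, a2, tolerance = 1e-12)
})
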