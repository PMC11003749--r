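test_that("ground-truth maps are deterministic and band-limited", {
  m1 <- make_ground_truth(grid_shape = c(48, 48), mm_per_pixel = 8 / 48,
                          seed = 3)
  m2 <- make_ground_truth(grid_shape = c(48, 48), mm_per_pixel = 8 / 48,
                          seed = 3)
  expect_identical(m1, m2)
  m3 <- make_ground_truth(grid_shape = c(48, 48), mm_per_pixel = 8 / 48,
                          seed = 4)
  expect_false(identical(m1$theta, m3$theta))

  # columnar component A exp(2 i theta) carries < 1% power outside the band
  f <- m1$A * exp(2i * m1$theta * pi / 180)
  pw <- Mod(stats::fft(f))^2
  fr <- vsdmask:::fft_freq(48, 8 / 48)
  rho <- sqrt(outer(fr^2, fr^2, "+"))
  out_band <- sum(pw[rho < 0.8 | rho > 3.0]) / sum(pw)
  expect_lt(out_band, 0.01)

  expect_true(all(m1$theta >= 0 & m1$theta < 180))
  expect_true(all(m1$A >= 0))
})

test_that("envelope sigma is recovered by refitting the generated envelope", {
  maps <- make_ground_truth(grid_shape = c(64, 64), mm_per_pixel = 8 / 64,
                            envelope_sigma_mm = 1.0, seed = 9)
  fit <- fit_retinotopic_template(maps$envelope,
                                  mm_per_pixel = maps$mm_per_pixel)
  expect_lt(abs(fit$params$sigma_major_mm - 1.0), 0.02)
  expect_lt(abs(fit$params$sigma_minor_mm - 1.0), 0.02)
})

test_that("column band beyond Nyquist is rejected", {
  expect_error(make_ground_truth(grid_shape = c(32, 32), mm_per_pixel = 0.25,
                                 column_band = c(0.8, 3.0)),
               "Nyquist")
})

test_that("renders express columnar preference and the retinotopic envelope", {
  maps <- small_maps()
  # 90-deg background: 90-preferring pixels respond more than 0-preferring
  dff <- small_bg_dff(90)
  resp <- apply(dff$frames[, , frames_in_window(dff, c(100, 200))],
                c(1, 2), mean)
  near90 <- abs(orientation_difference(maps$theta, 90)) < 15
  near0 <- abs(orientation_difference(maps$theta, 0)) < 15
  expect_gt(mean(resp[near90]), mean(resp[near0]))

  # target-only, columnar depth 0: profile proportional to the envelope
  maps_c <- make_ground_truth(grid_shape = c(48, 48), mm_per_pixel = 8 / 48,
                              envelope_center = c(25, 25), seed = 5)
  st <- render_trial_stack(stimulus_spec(target_contrast = 0.24), maps_c,
                           columnar_depth = 0, noise = noiseless(), seed = 1)
  d <- delta_f_over_f(st)
  peak_frame <- d$frames[, , which.max(apply(d$frames, 3, max))]
  expect_equal(which.max(peak_frame),
               which.max(maps_c$envelope))
  expect_gt(stats::cor(as.vector(peak_frame), as.vector(maps_c$envelope)),
            0.999999)
})

test_that("renders are pure functions of their seed", {
  maps <- small_maps()
  s1 <- render_trial_stack(stimulus_spec(background_contrast = 0.12),
                           maps, seed = 42)
  s2 <- render_trial_stack(stimulus_spec(background_contrast = 0.12),
                           maps, seed = 42)
  expect_identical(s1$frames, s2$frames)
})

test_that("injected motion raises temporal variance at high-gradient pixels", {
  maps <- small_maps()
  st_still <- render_trial_stack(stimulus_spec(), maps, noise = noiseless(),
                                 seed = 2, n_frames = 50)
  st_mov <- render_trial_stack(stimulus_spec(), maps, noise = noiseless(),
                               motion = motion_spec(amplitude_px = 0.5,
                                                    frequency_hz = 1.5),
                               seed = 2, n_frames = 50)
  g <- vsdmask:::spatial_gradient(vsdmask:::baseline_pattern(c(48, 48),
                                                             maps$seed))
  gm <- sqrt(g$row^2 + g$col^2)
  hi <- gm > stats::quantile(gm, 0.8)
  v_mov <- apply(st_mov$frames, c(1, 2), stats::var)
  v_still <- apply(st_still$frames, c(1, 2), stats::var)
  expect_gt(sum(v_mov[hi]), sum(v_still[hi]) + 1e-6)
})

test_that("behavioral simulator follows the Gaussian-observer probabilities", {
  # d' = 0, criterion = 0: hit and false-alarm rates both near 0.5
  b0 <- simulate_behavior_outcome(0, 0, rep(c(TRUE, FALSE), 10000), seed = 1)
  expect_lt(abs(mean(b0$outcome[b0$target_present] == "hit") - 0.5), 0.02)
  expect_lt(abs(mean(b0$outcome[!b0$target_present] == "false_alarm") - 0.5),
            0.02)

  # extreme sensitivity: hits -> 1, false alarms -> 0
  bL <- simulate_behavior_outcome(20, 0, rep(c(TRUE, FALSE), 500), seed = 2)
  expect_true(all(bL$outcome[bL$target_present] == "hit"))
  expect_true(all(bL$outcome[!bL$target_present] == "correct_reject"))

  # d' = 2: empirical hit rate matches pnorm(1) within 3 standard errors
  n <- 1e5
  b2 <- simulate_behavior_outcome(2, 0, rep(TRUE, n), seed = 3)
  p <- stats::pnorm(1)
  se3 <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(b2$outcome == "hit") - p), se3)
})

test_that("reaction times exist exactly on saccade outcomes and respect the floor", {
  b <- simulate_behavior_outcome(1, 0, rep(c(TRUE, FALSE), 2000), seed = 4)
  sac <- b$outcome %in% c("hit", "false_alarm")
  expect_true(all(!is.na(b$rt_ms[sac])))
  expect_true(all(is.na(b$rt_ms[!sac])))
  expect_true(all(b$rt_ms[sac] >= 75))
})

test_that("session bookkeeping: balanced blocks and byte-identical repeats", {
  des <- session_design(orientations = seq(-75, 90, by = 15),
                        trials_per_orientation = 20)
  s1 <- simulate_session(des, small_maps(), seed = 6, render_images = FALSE)
  det <- s1$trials[s1$trials$block == "detection", ]
  expect_equal(nrow(det), 12 * 20)
  expect_equal(mean(det$target_present), 0.5)
  per_o <- table(det$background_orientation)
  expect_true(all(per_o == 20))

  s2 <- simulate_session(des, small_maps(), seed = 6, render_images = FALSE)
  expect_identical(s1$trials, s2$trials)
})

test_that("trial-log round trip through CSV preserves the log", {
  s <- simulate_session(session_design(trials_per_orientation = 2),
                        small_maps(), seed = 8, render_images = FALSE)
  path <- tempfile(fileext = ".csv")
  write_trial_log(s, path)
  back <- read_trial_log(path)
  expect_equal(back$outcome, s$trials$outcome)
  expect_equal(back$rt_ms, s$trials$rt_ms)
})
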