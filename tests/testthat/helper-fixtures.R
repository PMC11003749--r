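# shared synthetic fixtures, built once per test run and memoized
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small maps: 48 px over 8 mm keeps the 0.8-3.0 cycles/mm band below Nyquist
small_maps <- function() {
  memo("small_maps", function() {
    make_ground_truth(grid_shape = c(48, 48), mm_per_pixel = 8 / 48,
                      envelope_sigma_mm = 1.0, seed = 5)
  })
}

flash_train <- function() list(rate = 5, on_ms = 60, train_ms = 1000)

noiseless <- function() noise_spec(white_sd = 0, corr_sd = 0)

# noiseless fixation-block template + columnar map on the small grid
small_templates <- function() {
  memo("small_templates", function() {
    maps <- small_maps()
    tstack <- render_trial_stack(
      stimulus_spec(target_contrast = 0.24), maps, columnar_depth = 0,
      noise = noiseless(), seed = 1, flash = flash_train())
    fm <- extract_flash_response(delta_f_over_f(tstack))
    template <- fit_retinotopic_template(fm)
    orients <- seq(-75, 90, by = 15)
    grats <- lapply(orients, function(o) {
      extract_flash_response(delta_f_over_f(render_trial_stack(
        stimulus_spec(background_contrast = 1, background_orientation = o),
        maps, noise = noiseless(), seed = 1, flash = flash_train())))
    })
    cmap <- fit_columnar_map(grats, orients, template)
    list(maps = maps, template = template, cmap = cmap)
  })
}

# noiseless background-only dF/F render on the small grid
small_bg_dff <- function(orientation, contrast = 0.12, depth = 0.15) {
  delta_f_over_f(render_trial_stack(
    stimulus_spec(background_contrast = contrast,
                  background_orientation = orientation),
    small_maps(), columnar_depth = depth, noise = noiseless(), seed = 1))
}

expect_orientation_close <- function(a, b, tol) {
  expect_lt(abs(orientation_difference(a, b)), tol)
}
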