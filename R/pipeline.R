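#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis in one serializable
#' list: session design, generator parameters, preprocessing and decoding
#' settings, statistics windows, model parameters, and the master seed. A
#' run is reproducible from the configuration alone.
#'
#' @param grid_shape,mm_per_pixel,envelope_sigma_mm,column_band ground-truth
#'   map geometry.
#' @param design a [session_design()].
#' @param masking_profile named `c(A=, sigma=, c=)` d-prime masking law.
#' @param criterion observer bias.
#' @param response_gain,columnar_depth render signal parameters.
#' @param noise a [noise_spec()].
#' @param motion a [motion_spec()] or `NULL`.
#' @param band columnar spatial band, cycles/mm.
#' @param variance_floor_quantile decoder variance floor.
#' @param window_sd columnar inclusion ellipse, template SDs.
#' @param zscore_window,integrate_window ms pairs for normalization and
#'   response integration.
#' @param trend_alpha F-test level.
#' @param coherence_threshold trajectory masking threshold.
#' @param model a [norm_model_params()].
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_shape = c(128, 128), mm_per_pixel = 8 / 128,
                            envelope_sigma_mm = 1.0,
                            column_band = c(0.8, 3.0),
                            design = session_design(),
                            masking_profile = c(A = 1.5, sigma = 30,
                                                c = 2.5),
                            criterion = 0.5,
                            response_gain = 0.01, columnar_depth = 0.15,
                            noise = noise_spec(), motion = NULL,
                            band = c(0.8, 3.0),
                            variance_floor_quantile = 0.01, window_sd = 2,
                            zscore_window = c(50, 250),
                            integrate_window = c(50, 200),
                            trend_alpha = 0.05,
                            coherence_threshold = 0.2,
                            model = norm_model_params(), seed = 1) {
  if (design$trials_per_orientation < 1) stopf("design has zero trials")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar overrides in the file are applied on top of the defaults of
#' [pipeline_config()]; nested blocks `design`, `noise`, `motion`, `model`
#' are passed to their respective constructors.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  plain <- setdiff(names(y), c("design", "noise", "motion", "model"))
  args[plain] <- y[plain]
  if (!is.null(y$design)) args$design <- do.call(session_design, y$design)
  if (!is.null(y$noise)) args$noise <- do.call(noise_spec, y$noise)
  if (!is.null(y$motion)) args$motion <- do.call(motion_spec, y$motion)
  if (!is.null(y$model)) args$model <- do.call(norm_model_params, y$model)
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes every stage in order: ground-truth simulation, rendering,
#' motion stabilization and dF/F, template estimation from the fixation
#' block, reliability-weighted decoding of the detection block, z-score
#' normalization and reaction-time censoring, per-orientation trend fits and
#' neural-behavior correlation, behavioral summary with the masking fit,
#' population-vector trajectories, and the normalization-model simulation
#' with its behavior correlation. When `output_dir` is given, per-stage CSV
#' tables and a JSON summary are written; with `figures = TRUE` basic PNG
#' panels are rendered as well.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for CSV/JSON (created if needed).
#' @param figures write PNG panels (requires `output_dir`).
#' @return (invisibly) a list bundle with all stage outputs and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         figures = FALSE) {
  maps <- make_ground_truth(config$grid_shape, config$mm_per_pixel,
                            envelope_sigma_mm = config$envelope_sigma_mm,
                            column_band = config$column_band,
                            seed = config$seed)
  session <- simulate_session(config$design, maps,
                              masking_profile = config$masking_profile,
                              criterion = config$criterion,
                              noise = config$noise, motion = config$motion,
                              response_gain = config$response_gain,
                              columnar_depth = config$columnar_depth,
                              seed = config$seed)

  prep <- function(stack) {
    mo <- estimate_motion(stack)
    delta_f_over_f(stabilize(stack, mo))
  }

  trials <- session$trials
  # templates from the fixation block; repetitions of the same stimulus are
  # averaged coherently (stacks first, amplitude after) to avoid the
  # positive bias of noise in amplitude maps
  avg_prep <- function(idx) {
    acc <- NULL
    for (i in idx) {
      s <- prep(session$stacks[[i]])
      acc <- if (is.null(acc)) s else {
        acc$frames <- acc$frames + s$frames; acc
      }
    }
    acc$frames <- acc$frames / length(idx)
    acc
  }
  fix_t <- which(trials$stim_kind == "target_flash")
  fix_g <- which(trials$stim_kind == "grating_flash")
  target_amp <- extract_flash_response(avg_prep(fix_t),
                                       config$design$flash$rate)
  template <- fit_retinotopic_template(target_amp)
  grat_or <- sort(unique(trials$background_orientation[fix_g]))
  grat_amps <- lapply(grat_or, function(o) {
    extract_flash_response(
      avg_prep(fix_g[trials$background_orientation[fix_g] == o]),
      config$design$flash$rate)
  })
  cmap <- fit_columnar_map(grat_amps, grat_or, template,
                           band = config$band,
                           window_sd = config$window_sd)

  # detection block: dF/F, variance maps, decoding
  det <- which(trials$block == "detection")
  det_dff <- lapply(det, function(i) prep(session$stacks[[i]]))
  cond <- interaction(trials$background_orientation[det],
                      trials$target_present[det], drop = TRUE)
  var_ret <- estimate_pixel_variance(det_dff, cond, "retinotopic",
                                     floor_quantile =
                                       config$variance_floor_quantile)
  var_col <- estimate_pixel_variance(det_dff, cond, "columnar",
                                     band = config$band,
                                     mm_per_pixel = maps$mm_per_pixel,
                                     floor_quantile =
                                       config$variance_floor_quantile)

  dec_ret <- lapply(det_dff, decode_retinotopic, template = template,
                    var = var_ret)
  dec_axis <- lapply(det_dff, decode_columnar_axis, cmap = cmap,
                     var = var_col)
  dec_pop <- lapply(det_dff, decode_population, cmap = cmap, var = var_col)
  rm(det_dff)

  dec_ret <- zscore_normalize(dec_ret, cond, window = config$zscore_window)
  dec_axis <- zscore_normalize(dec_axis, cond, window = config$zscore_window)

  rt <- trials$rt_ms[det]
  ret_by_cond <- condition_mean_series(dec_ret, cond, rt)
  axis_by_cond <- condition_mean_series(dec_axis, cond, rt)
  pop_by_cond <- condition_mean_series(dec_pop, cond, rt)

  # target-evoked series and integrated per-orientation response
  orients <- sort(unique(trials$background_orientation[det]))
  te_axis <- lapply(orients, function(o) {
    key_tb <- cond_key(o, TRUE); key_b <- cond_key(o, FALSE)
    if (is.null(axis_by_cond[[key_tb]]) || is.null(axis_by_cond[[key_b]])) {
      return(NULL)
    }
    target_evoked_series(axis_by_cond[[key_tb]], axis_by_cond[[key_b]])
  })
  names(te_axis) <- orients
  te_int <- vapply(te_axis, function(s) {
    if (is.null(s)) return(NA_real_)
    sel <- s$times >= config$integrate_window[1] &
      s$times <= config$integrate_window[2]
    mean(s$values[sel], na.rm = TRUE)
  }, numeric(1))

  behav <- behavior_summary(trials)
  bo <- behav$by_orientation
  nt_per_o <- bo$n_hit + bo$n_miss + bo$n_cr + bo$n_fa
  m <- match(orients, bo$orientation)
  ok <- is.finite(te_int) & !is.na(m)
  nb_cor <- if (sum(ok) >= 3) {
    weighted_correlation(te_int[ok], bo$dprime[m[ok]], nt_per_o[m[ok]])
  } else NULL
  trend <- if (sum(ok) >= 5) {
    fit_orientation_trend(te_int[ok], orients[ok], config$trend_alpha)
  } else NULL

  trajectories <- lapply(pop_by_cond, trajectory_summary,
                         coherence_threshold = config$coherence_threshold)

  # normalization model stage
  model_set <- simulate_model_set(
    background_orientations = sort(unique(abs(orients))),
    target_contrast = config$design$target_contrast,
    background_contrast = config$design$background_contrast,
    params = config$model)
  mb_behavior <- stats::predict(
    behav$masking_fit, sort(unique(abs(orients))))
  mb_cor <- model_behavior_correlation(model_set, mb_behavior)
  early <- mb_cor$rho[mb_cor$t_ms <= 80]
  late <- mb_cor$rho[mb_cor$t_ms >= 150 & mb_cor$t_ms <= 250]

  summary <- list(
    seed = config$seed,
    n_trials = nrow(trials),
    template_center = template$params$center,
    template_sigma_mm = c(template$params$sigma_major_mm,
                          template$params$sigma_minor_mm),
    map_circular_correlation =
      circular_orientation_cor(cmap$theta[cmap$mask],
                               maps$theta[cmap$mask]),
    behavior = list(masking_fit = if (!is.null(behav$masking_fit)) {
      as.list(stats::coef(behav$masking_fit))
    } else NULL,
      baseline_dprime = behav$baseline_dprime),
    neural_behavior_rho = if (!is.null(nb_cor)) nb_cor$rho else NA,
    trend_model = if (!is.null(trend)) trend$model else NA,
    model_popvec_peak_ms = model_set$b[[1]]$times[
      which.max(model_popvec_magnitude(model_set$b[[1]]))],
    model_correlation_early_negative = all(early < 0, na.rm = TRUE),
    model_correlation_late_positive = all(late > 0, na.rm = TRUE))

  bundle <- list(config = config, maps = maps, session = session,
                 template = template, columnar_map = cmap,
                 variance = list(retinotopic = var_ret, columnar = var_col),
                 decoded = list(retinotopic = ret_by_cond,
                                axis = axis_by_cond,
                                population = pop_by_cond),
                 target_evoked = te_axis, integrated_axis = te_int,
                 behavior = behav, neural_behavior_cor = nb_cor,
                 trend = trend, trajectories = trajectories,
                 model_set = model_set, model_behavior_cor = mb_cor,
                 summary = summary)

  if (!is.null(output_dir)) {
    write_pipeline_outputs(bundle, output_dir, figures)
  }
  invisible(bundle)
}

cond_key <- function(orientation, target_present) {
  paste0(orientation, ".", target_present)
}

# reaction-time-censored condition-mean series for a list of per-trial series
condition_mean_series <- function(series, cond, rt) {
  out <- list()
  for (g in split(seq_along(series), cond)) {
    if (!length(g)) next
    key <- as.character(cond[g[1]])
    out[[key]] <- censor_after_saccade(series[g], rt[g], mode = "framewise")
  }
  out
}

write_pipeline_outputs <- function(bundle, output_dir, figures = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_log(bundle$session, file.path(output_dir, "trial_log.csv"))
  utils::write.csv(bundle$behavior$by_orientation,
                   file.path(output_dir, "behavior_by_orientation.csv"),
                   row.names = FALSE)
  te_tab <- do.call(rbind, lapply(names(bundle$target_evoked), function(o) {
    s <- bundle$target_evoked[[o]]
    if (is.null(s)) return(NULL)
    data.frame(background_orientation = as.numeric(o), t_ms = s$times,
               value = s$values)
  }))
  if (!is.null(te_tab)) {
    utils::write.csv(te_tab,
                     file.path(output_dir, "target_evoked_axis.csv"),
                     row.names = FALSE)
  }
  traj_tab <- do.call(rbind, lapply(names(bundle$trajectories),
                                    function(k) {
    cbind(condition = k, bundle$trajectories[[k]])
  }))
  utils::write.csv(traj_tab, file.path(output_dir, "trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$model_behavior_cor,
                   file.path(output_dir, "model_behavior_correlation.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$summary,
                       file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (figures) {
    grDevices::png(file.path(output_dir, "trajectories.png"), 700, 700)
    first <- bundle$trajectories[[1]]
    plot(first, col = "steelblue", lwd = 2)
    grDevices::dev.off()
    grDevices::png(file.path(output_dir, "masking_curve.png"), 700, 500)
    bo <- bundle$behavior$by_orientation
    graphics::plot(bo$orientation, bo$dprime, pch = 16,
                   xlab = "background orientation (deg)", ylab = "d'")
    if (!is.null(bundle$behavior$masking_fit)) {
      th <- seq(min(bo$orientation), max(bo$orientation), length.out = 181)
      graphics::lines(th, stats::predict(bundle$behavior$masking_fit, th))
    }
    grDevices::dev.off()
  }
  invisible(output_dir)
}
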