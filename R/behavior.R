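#' Signal-detection sensitivity and criterion from trial counts
#'
#' `d' = qnorm(P_hit) - qnorm(P_fa)` and
#' `criterion = -(qnorm(P_hit) + qnorm(P_fa)) / 2` for an equal-variance
#' Gaussian observer. To keep every condition finite (e.g. blocks with no
#' false alarms), all proportions are first rescaled into `[0.005, 0.995]`
#' by `P_hat = 0.005 + 0.99 P`; the rescaling is applied unconditionally.
#'
#' @param hits,misses,correct_rejects,false_alarms trial counts (vectors are
#'   processed elementwise).
#' @return data.frame with columns `dprime`, `criterion`, `p_hit`, `p_fa`
#'   (the scaled proportions).
#' @export
dprime_criterion <- function(hits, misses, correct_rejects, false_alarms) {
  n_sig <- hits + misses
  n_noise <- correct_rejects + false_alarms
  if (any(n_sig < 1) || any(n_noise < 1)) {
    stopf("each condition needs >= 1 target-present and >= 1 target-absent trial")
  }
  ph <- 0.005 + 0.99 * (hits / n_sig)
  pf <- 0.005 + 0.99 * (false_alarms / n_noise)
  zh <- stats::qnorm(ph)
  zf <- stats::qnorm(pf)
  data.frame(dprime = zh - zf, criterion = -(zh + zf) / 2,
             p_hit = ph, p_fa = pf)
}

#' Unbiased maximum percent correct implied by d-prime
#'
#' `PCmax = pnorm(d' / 2)`: the percent correct an unbiased observer with the
#' given sensitivity would attain.
#'
#' @param dprime numeric vector.
#' @return proportions in `(0, 1)`.
#' @export
pc_max <- function(dprime) {
  stats::pnorm(dprime / 2)
}

#' Fit the inverted-Gaussian masking curve
#'
#' Detection sensitivity across background orientation is fitted with an
#' inverted, dc-shifted Gaussian, `d'(theta) = c - A exp(-theta^2 / (2
#' sigma^2))` (minimum at 0 deg, where the background matches the target),
#' by least squares weighted by trial counts, with `A >= 0` enforced.
#'
#' @param dprime per-orientation sensitivities.
#' @param orientations background orientations in degrees.
#' @param trial_counts optional weights. The fit is on signed orientation;
#'   pass `abs(orientations)` to pool clockwise and anticlockwise
#'   disparities, or fit the two signs separately.
#' @return an object of class `masking_fit` with `coefficients` (A, sigma,
#'   c), `fitted`, and the inputs.
#' @export
fit_masking_curve <- function(dprime, orientations, trial_counts = NULL) {
  dprime <- unname(dprime)
  orientations <- unname(orientations)
  n <- length(dprime)
  if (length(orientations) != n) stopf("one orientation per d-prime")
  if (n < 5) stopf("need >= 5 orientations")
  w <- if (is.null(trial_counts)) rep(1, n) else trial_counts
  df0 <- data.frame(d = dprime, th = orientations, w = w)
  far <- dprime[which.max(abs(orientations))]
  near <- dprime[which.min(abs(orientations))]
  start <- list(c0 = far, A = max(far - near, 0.1), sg = 30)
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ c0 - A * exp(-th^2 / (2 * sg^2)), data = df0,
                      start = start, weights = w,
                      lower = c(c0 = -Inf, A = 0, sg = 1),
                      upper = c(c0 = Inf, A = Inf, sg = 1000),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # moment-based fallback: report the initialization with a diagnostic
    cf <- c(A = start$A, sigma = start$sg, c = start$c0)
    return(structure(list(coefficients = cf,
                          fitted = cf[["c"]] - cf[["A"]] *
                            exp(-orientations^2 / (2 * cf[["sigma"]]^2)),
                          dprime = dprime, orientations = orientations,
                          weights = w, converged = FALSE),
                     class = "masking_fit"))
  }
  cf0 <- stats::coef(fit)
  cf <- c(A = unname(cf0[["A"]]), sigma = unname(cf0[["sg"]]),
          c = unname(cf0[["c0"]]))
  structure(list(coefficients = cf, fitted = stats::fitted(fit),
                 dprime = dprime, orientations = orientations, weights = w,
                 converged = TRUE),
            class = "masking_fit")
}

#' @export
coef.masking_fit <- function(object, ...) object$coefficients

#' @export
print.masking_fit <- function(x, ...) {
  cat(sprintf("<masking_fit> d'(theta) = %.3g - %.3g exp(-theta^2/(2 %.3g^2))%s\n",
              x$coefficients[["c"]], x$coefficients[["A"]],
              x$coefficients[["sigma"]],
              if (x$converged) "" else " [fallback initialization]"))
  invisible(x)
}

#' @export
predict.masking_fit <- function(object, orientations = object$orientations,
                                ...) {
  cf <- object$coefficients
  cf[["c"]] - cf[["A"]] * exp(-orientations^2 / (2 * cf[["sigma"]]^2))
}

#' Per-orientation reaction-time summary
#'
#' Mean and standard error of the reaction time over hit trials, per
#' background orientation. Reaction times exist only on saccade trials, and
#' the summary follows the convention of using hits (false alarms also end
#' in saccades but are excluded). Orientations with no hits are absent from
#' the output.
#'
#' @param trials trial-log data.frame with columns `background_orientation`,
#'   `outcome`, `rt_ms`.
#' @return data.frame with columns `orientation`, `n`, `rt_mean_ms`,
#'   `rt_sem_ms`.
#' @export
reaction_time_summary <- function(trials) {
  h <- trials[trials$outcome %in% "hit" & !is.na(trials$rt_ms), ]
  if (!nrow(h)) {
    return(data.frame(orientation = numeric(0), n = integer(0),
                      rt_mean_ms = numeric(0), rt_sem_ms = numeric(0)))
  }
  out <- do.call(rbind, lapply(split(h, h$background_orientation),
                               function(g) {
    n <- nrow(g)
    data.frame(orientation = g$background_orientation[1], n = n,
               rt_mean_ms = mean(g$rt_ms),
               rt_sem_ms = if (n > 1) stats::sd(g$rt_ms) / sqrt(n) else 0)
  }))
  rownames(out) <- NULL
  out[order(out$orientation), ]
}

#' Behavioral summary of a detection session
#'
#' Per-orientation outcome counts, d-prime, criterion and reaction-time
#' statistics for the detection block of a trial log, a baseline d-prime
#' from uniform-background (reference) trials when present, and the
#' inverted-Gaussian masking fit across orientations.
#'
#' @param trials a trial-log data.frame (see [simulate_session()]) or a
#'   `vsd_session`.
#' @return an object of class `behavior_summary`: `by_orientation`
#'   data.frame, `masking_fit`, `baseline_dprime` (or `NA`).
#' @export
behavior_summary <- function(trials) {
  if (inherits(trials, "vsd_session")) trials <- trials$trials
  det <- trials[trials$block == "detection", ]
  if (!nrow(det)) stopf("no detection trials")
  counts <- do.call(rbind, lapply(split(det, det$background_orientation),
                                  function(g) {
    data.frame(orientation = g$background_orientation[1],
               n_hit = sum(g$outcome == "hit"),
               n_miss = sum(g$outcome == "miss"),
               n_cr = sum(g$outcome == "correct_reject"),
               n_fa = sum(g$outcome == "false_alarm"))
  }))
  rownames(counts) <- NULL
  dc <- dprime_criterion(counts$n_hit, counts$n_miss, counts$n_cr,
                         counts$n_fa)
  counts$dprime <- dc$dprime
  counts$criterion <- dc$criterion
  rts <- reaction_time_summary(det)
  counts <- merge(counts, rts[, c("orientation", "rt_mean_ms", "rt_sem_ms")],
                  by = "orientation", all.x = TRUE)
  counts <- counts[order(counts$orientation), ]

  nt <- counts$n_hit + counts$n_miss + counts$n_cr + counts$n_fa
  mfit <- if (nrow(counts) >= 5) {
    fit_masking_curve(counts$dprime, counts$orientation, nt)
  } else NULL

  ref <- trials[trials$block == "reference" &
                  trials$outcome %in% c("hit", "miss", "correct_reject",
                                        "false_alarm"), ]
  baseline <- NA_real_
  if (nrow(ref) && any(ref$target_present) && any(!ref$target_present)) {
    baseline <- dprime_criterion(sum(ref$outcome == "hit"),
                                 sum(ref$outcome == "miss"),
                                 sum(ref$outcome == "correct_reject"),
                                 sum(ref$outcome == "false_alarm"))$dprime
  }
  structure(list(by_orientation = counts, masking_fit = mfit,
                 baseline_dprime = baseline),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary>\n")
  print(x$by_orientation, row.names = FALSE)
  if (!is.null(x$masking_fit)) print(x$masking_fit)
  invisible(x)
}
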