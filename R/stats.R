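#' Cross-experiment response scaling by SVD
#'
#' Response amplitudes vary across experiment days with dye-staining
#' effectiveness. Each experiment's target-only reference responses (time x
#' contrast matrices) are interpolated to the union of tested contrasts,
#' stacked, and decomposed by SVD over the pooling window. The first
#' component's loadings measure each experiment's response magnitude; every
#' experiment is scaled to match the one with the largest loading, and the
#' pooling reliability weight is `w_exp = 1 / scale^2`.
#'
#' @param responses list of numeric matrices, one per experiment, time x
#'   contrast.
#' @param contrasts list of contrast vectors matching the matrix columns.
#' @param times frame times (ms) for the matrix rows, shared by experiments.
#' @param window ms pair over which the SVD is taken (-100 to 200 default).
#' @return an object of class `pooling_scale`: `svd1_coefficients`,
#'   `scale_factors`, `weights`, `dynamics` (the first temporal-contrast
#'   component), `contrast_grid`.
#' @export
svd_pool_scale <- function(responses, contrasts, times = NULL,
                           window = c(-100, 200)) {
  n_exp <- length(responses)
  if (n_exp < 1) stopf("at least one experiment required")
  if (length(contrasts) != n_exp) stopf("one contrast vector per experiment")
  nt <- nrow(responses[[1]])
  if (is.null(times)) times <- seq_len(nt)
  keep <- which(times >= window[1] & times <= window[2])
  if (!length(keep)) stopf("pooling window covers no frames")

  grid <- sort(unique(unlist(contrasts)))
  interp <- lapply(seq_len(n_exp), function(i) {
    m <- responses[[i]][keep, , drop = FALSE]
    cs <- contrasts[[i]]
    if (length(cs) == 1) {
      out <- m[, rep(1, length(grid)), drop = FALSE]
    } else {
      if (min(cs) > min(grid) || max(cs) < max(grid)) {
        warning(sprintf(
          "experiment %d lacks contrasts at the grid edge; values clamped", i),
          call. = FALSE)
      }
      out <- t(apply(m, 1, function(rv) {
        stats::approx(cs, rv, xout = grid, rule = 2)$y
      }))
    }
    as.vector(out)
  })
  x <- do.call(rbind, interp)
  if (all(abs(x) < .Machine$double.eps)) stopf("reference responses are rank 0")

  s <- svd(x)
  load1 <- s$u[, 1] * s$d[1]
  if (sum(s$v[, 1]) < 0) load1 <- -load1
  if (any(load1 <= 0)) {
    warning("non-positive SVD1 coefficient; pooling scale unreliable for that experiment",
            call. = FALSE)
  }
  scale_factors <- max(load1) / load1
  structure(list(svd1_coefficients = load1, scale_factors = scale_factors,
                 weights = 1 / scale_factors^2,
                 dynamics = s$v[, 1], contrast_grid = grid),
            class = "pooling_scale")
}

#' @export
print.pooling_scale <- function(x, ...) {
  cat(sprintf("<pooling_scale> %d experiment(s); scales %s\n",
              length(x$scale_factors),
              paste(signif(x$scale_factors, 3), collapse = ", ")))
  invisible(x)
}

#' Reliability-weighted pooled mean and SD
#'
#' The estimator used when pooling decoded responses across experiments:
#' `mean = (1/n) sum w_i r_i` and
#' `sd = sqrt((1/n) sum (w_i r_i - mean)^2)`, with the weights inside both
#' sums and divisor `n`. Note this is not the conventional weighted mean; it
#' treats the weighted observations `w_i r_i` as the pooled sample.
#'
#' @param values numeric vector of per-trial values.
#' @param weights positive weights, recycled to `length(values)`.
#' @return named vector `c(mean =, sd =)`.
#' @export
weighted_mean_sd <- function(values, weights = 1) {
  n <- length(values)
  if (n == 0) stopf("no values to pool")
  weights <- rep_len(weights, n)
  if (any(weights <= 0)) stopf("weights must be positive")
  wr <- weights * values
  m <- sum(wr) / n
  c(mean = m, sd = sqrt(sum((wr - m)^2) / n))
}

#' Modified z-score normalization of decoded responses
#'
#' Expresses decoded responses in units of their own trial-to-trial residual
#' variability: responses are grouped by condition, each condition's mean
#' time course is subtracted, the residuals within the normalization window
#' (50-250 ms post onset by default) are pooled with the experiment
#' reliability weights, and every series is divided by the pooled SD.
#'
#' @param series list of `decoded_series` (one per trial) or a trials x
#'   frames matrix.
#' @param condition_labels one label per trial.
#' @param times frame times if `series` is a matrix.
#' @param window ms pair of the residual-pooling window.
#' @param weights per-trial reliability weights (e.g. the experiment's
#'   `w_exp` repeated over its trials).
#' @return the input with every value divided by the pooled SD; the divisor
#'   is attached as attribute `"pooled_sd"`.
#' @export
zscore_normalize <- function(series, condition_labels, times = NULL,
                             window = c(50, 250), weights = 1) {
  if (is.list(series)) {
    times <- series[[1]]$times
    mat <- do.call(rbind, lapply(series, function(s) {
      if (is.matrix(s$values)) stopf("per-channel series: normalize each channel")
      s$values
    }))
  } else {
    mat <- series
    if (is.null(times)) stopf("times required for matrix input")
  }
  keep <- which(times >= window[1] & times <= window[2])
  if (!length(keep)) stopf("window covers no frames")
  weights <- rep_len(weights, nrow(mat))
  resid <- mat
  for (g in split(seq_len(nrow(mat)), condition_labels)) {
    resid[g, ] <- sweep(mat[g, , drop = FALSE], 2,
                        colMeans(mat[g, , drop = FALSE]))
  }
  rw <- as.vector(resid[, keep, drop = FALSE]) *
    rep(weights, times = length(keep))
  sd_pool <- sqrt(mean((rw - mean(rw))^2))
  if (sd_pool <= 0) stopf("zero residual SD in the normalization window")
  if (is.list(series)) {
    out <- lapply(series, function(s) {
      s$values <- s$values / sd_pool
      s$units <- "zscore"
      s
    })
  } else {
    out <- mat / sd_pool
  }
  attr(out, "pooled_sd") <- sd_pool
  out
}

#' Censor decoded responses beyond the reaction time
#'
#' Frames after the saccade may contain eye-movement signals, so each trial
#' contributes only up to its reaction-time frame. In `"integrate"` mode each
#' trial is reduced to the mean of its values over frames from stimulus onset
#' up to the RT (the full post-onset series when no saccade occurred). In
#' `"framewise"` mode, cross-trial frame averages are formed with each trial
#' dropping out beyond its RT frame.
#'
#' @param series list of `decoded_series` (scalar or population), one per
#'   trial.
#' @param rt reaction times in ms (`NA` for trials without a saccade).
#' @param mode `"integrate"` or `"framewise"`.
#' @return integrate mode: numeric vector (or trials x channels matrix) of
#'   per-trial means. framewise mode: a `decoded_series` of censored
#'   cross-trial means, with attribute `"n_contributing"`.
#' @export
censor_after_saccade <- function(series, rt, mode = c("integrate",
                                                      "framewise")) {
  mode <- match.arg(mode)
  if (length(series) != length(rt)) stopf("one rt per trial required")
  bad <- which(!is.na(rt) & rt < 0)
  if (length(bad)) {
    warning(sprintf("%d trial(s) with rt before onset excluded",
                    length(bad)), call. = FALSE)
    series <- series[-bad]; rt <- rt[-bad]
  }
  if (!length(series)) stopf("no usable trials")
  times <- series[[1]]$times
  keep_frames <- function(r) is.na(r) | times <= r

  if (mode == "integrate") {
    post <- times >= 0
    out <- lapply(seq_along(series), function(i) {
      sel <- keep_frames(rt[i]) & post
      v <- series[[i]]$values
      if (is.matrix(v)) colMeans(v[sel, , drop = FALSE]) else mean(v[sel])
    })
    if (is.matrix(series[[1]]$values)) do.call(rbind, out) else unlist(out)
  } else {
    is_pop <- is.matrix(series[[1]]$values)
    nch <- if (is_pop) ncol(series[[1]]$values) else 1
    acc <- matrix(0, length(times), nch)
    cnt <- matrix(0, length(times), nch)
    for (i in seq_along(series)) {
      sel <- keep_frames(rt[i])
      v <- series[[i]]$values
      if (!is_pop) v <- matrix(v, ncol = 1)
      ok <- sel & !apply(v, 1, anyNA)
      acc[ok, ] <- acc[ok, ] + v[ok, , drop = FALSE]
      cnt[ok, ] <- cnt[ok, ] + 1
    }
    mean_v <- acc / cnt
    mean_v[cnt == 0] <- NA
    if (!is_pop) mean_v <- as.vector(mean_v)
    out <- decoded_series(mean_v, times, series[[1]]$scale,
                          channels = series[[1]]$channels,
                          units = series[[1]]$units)
    attr(out, "n_contributing") <- if (is_pop) cnt else as.vector(cnt)
    out
  }
}

#' Trial-count-weighted Pearson correlation
#'
#' The weighted correlation used to relate per-orientation neural responses
#' to behavioral sensitivity, with weights inside the covariance sums:
#' `cov(x, y; w) = sum (w_i (x_i - m_x)) (w_i (y_i - m_y)) / sum w_i` with
#' `m` the weighted mean, and
#' `rho = cov(x, y; w) / sqrt(cov(x, x; w) cov(y, y; w))`. Because unequal
#' weights reduce the information content, significance uses an entropy-based
#' effective sample size `n_eff = exp(-sum p_i log p_i)` (`p = w / sum w`;
#' `n_eff = n` at equal weights) and the t statistic
#' `t = rho sqrt((n_eff - 2) / (1 - rho^2))` with `n_eff - 2` (possibly
#' non-integer) degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors (e.g. per-orientation response and d-prime).
#' @param w positive weights (trial counts).
#' @return an object of class `weighted_cor`: `rho`, `n_eff`, `p_value`,
#'   `t`, `weights`, `defined`.
#' @export
weighted_correlation <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  if (length(y) != n || length(w) != n) stopf("x, y, w lengths differ")
  ok <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < 3) stopf("need >= 3 observations with positive weight")
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  cxy <- sum((w * (x - mx)) * (w * (y - my))) / sw
  cxx <- sum((w * (x - mx))^2) / sw
  cyy <- sum((w * (y - my))^2) / sw
  p <- w / sw
  n_eff <- exp(-sum(p * log(p)))
  if (cxx <= 0 || cyy <= 0) {
    out <- list(rho = NA_real_, n_eff = n_eff, p_value = NA_real_,
                t = NA_real_, weights = w, defined = FALSE)
    class(out) <- "weighted_cor"
    return(out)
  }
  rho <- cxy / sqrt(cxx * cyy)
  rho <- max(-1, min(1, rho))
  df <- n_eff - 2
  if (df <= 0) {
    # weights so concentrated that fewer than 2 effective observations
    # remain: the correlation is reported but untestable
    tv <- NA_real_
    pv <- NA_real_
  } else {
    tv <- if (abs(rho) >= 1) Inf * sign(rho) else rho * sqrt(df / (1 - rho^2))
    pv <- 2 * stats::pt(-abs(tv), df = df)
  }
  structure(list(rho = rho, n_eff = n_eff, p_value = pv, t = tv,
                 weights = w, defined = TRUE),
            class = "weighted_cor")
}

#' @export
print.weighted_cor <- function(x, ...) {
  if (!x$defined) {
    cat("<weighted_cor> undefined (zero weighted variance)\n")
  } else {
    cat(sprintf("<weighted_cor> rho = %.3f, n_eff = %.2f, p = %.3g\n",
                x$rho, x$n_eff, x$p_value))
  }
  invisible(x)
}

#' Flat-versus-Gaussian trend across background orientation
#'
#' Fits the per-orientation responses with both a line `r = m theta + c` and
#' a dc-shifted Gaussian `r = A exp(-theta^2 / (2 sigma^2)) + c`, and selects
#' the Gaussian only when the nested F test
#' `F = ((SS_line - SS_gau) / (df_line - df_gau)) / (SS_gau / df_gau)`
#' exceeds the critical value at level `alpha`.
#'
#' @param values per-orientation responses.
#' @param orientations degrees.
#' @param alpha significance level for the F test.
#' @return an object of class `trend_fit`: `model` ("flat" or "gaussian"),
#'   `params`, `F`, `df`, `p_value`, `chosen_by_f`, plus both fits' RSS.
#' @export
fit_orientation_trend <- function(values, orientations, alpha = 0.05) {
  values <- unname(values)
  orientations <- unname(orientations)
  n <- length(values)
  if (length(orientations) != n) stopf("one orientation per value")
  if (n < 5) stopf("need >= 5 orientations for the Gaussian trend")
  lin <- stats::lm(values ~ orientations)
  ss_lin <- sum(stats::residuals(lin)^2)
  df_lin <- n - 2

  df0 <- data.frame(v = values, th = orientations)
  a0 <- values[which.min(abs(orientations))] -
    values[which.max(abs(orientations))]
  gau <- tryCatch(
    minpack.lm::nlsLM(v ~ c0 + A * exp(-th^2 / (2 * sg^2)), data = df0,
                      start = list(c0 = mean(values),
                                   A = ifelse(abs(a0) > 0, a0, 0.1), sg = 30),
                      lower = c(c0 = -Inf, A = -Inf, sg = 1),
                      upper = c(c0 = Inf, A = Inf, sg = 1000),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(gau)) {
    return(structure(list(model = "flat",
                          params = c(m = unname(stats::coef(lin)[2]),
                                     c = unname(stats::coef(lin)[1])),
                          F = NA_real_, df = c(NA, df_lin),
                          p_value = NA_real_, chosen_by_f = FALSE,
                          ss = c(flat = ss_lin, gaussian = NA),
                          note = "gaussian fit did not converge"),
                     class = "trend_fit"))
  }
  ss_gau <- sum(stats::residuals(gau)^2)
  df_gau <- n - 3
  fstat <- ((ss_lin - ss_gau) / (df_lin - df_gau)) / (ss_gau / df_gau)
  pv <- stats::pf(fstat, df_lin - df_gau, df_gau, lower.tail = FALSE)
  choose_gau <- is.finite(fstat) &&
    fstat > stats::qf(1 - alpha, df_lin - df_gau, df_gau)
  cg <- stats::coef(gau)
  structure(list(
    model = if (choose_gau) "gaussian" else "flat",
    params = if (choose_gau) {
      c(A = unname(cg[["A"]]), sigma = unname(cg[["sg"]]),
        c = unname(cg[["c0"]]))
    } else {
      c(m = unname(stats::coef(lin)[2]), c = unname(stats::coef(lin)[1]))
    },
    gaussian_params = c(A = unname(cg[["A"]]), sigma = unname(cg[["sg"]]),
                        c = unname(cg[["c0"]])),
    F = fstat, df = c(df_lin - df_gau, df_gau), p_value = pv,
    chosen_by_f = choose_gau,
    ss = c(flat = ss_lin, gaussian = ss_gau)),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s model chosen (F = %.3g, p = %.3g)\n  params: %s\n",
              x$model, x$F, x$p_value,
              paste(names(x$params), signif(x$params, 4), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
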