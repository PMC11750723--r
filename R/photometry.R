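#' Two-channel fibre-photometry recording
#'
#' Container for a calcium-sensitive (470 nm excitation) and isosbestic
#' (405 nm excitation) channel pair sampled uniformly, with the stimulation
#' schedule.
#'
#' @param data A data frame with columns `time_s`, `sig470`, `iso405`
#'   (uniform sampling), or `NULL` to pass vectors.
#' @param time_s,sig470,iso405 Vectors used when `data` is `NULL`.
#' @param fs Sampling rate in Hz (default 130).
#' @param stim_onsets Stimulation onset times in seconds, within the
#'   recording.
#' @param stim_duration Stimulation epoch duration in seconds.
#' @return A tibble of class `photometry_recording` with attributes `fs`,
#'   `stim_onsets`, `stim_duration`.
#' @export
photometry_recording <- function(data = NULL, time_s = NULL, sig470 = NULL,
                                 iso405 = NULL, fs = 130, stim_onsets,
                                 stim_duration = 5) {
  if (is.null(data)) {
    data <- tibble(time_s = time_s, sig470 = sig470, iso405 = iso405)
  }
  if (!all(c("time_s", "sig470", "iso405") %in% names(data))) {
    abort_bad_arg("data", "have columns time_s, sig470, iso405")
  }
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  n <- nrow(data)
  if (n < 2) abort_bad_arg("data", "have at least two samples")
  dt <- diff(data$time_s)
  if (max(abs(dt - 1 / fs)) > 1e-6 / fs + 1e-9) {
    abort_bad_arg("data", sprintf("be uniformly sampled at fs = %g Hz", fs))
  }
  check_numeric_vec(stim_onsets, "stim_onsets")
  if (any(stim_onsets < min(data$time_s)) ||
      any(stim_onsets > max(data$time_s))) {
    abort_bad_arg("stim_onsets", "lie within the recording")
  }
  check_number(stim_duration, "stim_duration", min = 0, strict_min = TRUE)
  out <- as_tibble(data)
  class(out) <- c("photometry_recording", class(out))
  attr(out, "fs") <- fs
  attr(out, "stim_onsets") <- sort(stim_onsets)
  attr(out, "stim_duration") <- stim_duration
  out
}

pm_attrs <- function(rec) {
  list(fs = attr(rec, "fs"), stim_onsets = attr(rec, "stim_onsets"),
       stim_duration = attr(rec, "stim_duration"))
}

restore_pm <- function(data, template) {
  out <- as_tibble(data)
  class(out) <- c("photometry_recording", class(tibble()))
  a <- pm_attrs(template)
  attr(out, "fs") <- a$fs
  attr(out, "stim_onsets") <- a$stim_onsets
  attr(out, "stim_duration") <- a$stim_duration
  out
}

#' Zero-phase Butterworth low-pass filter of both channels
#'
#' Second-order Butterworth low-pass (25 Hz by default) applied
#' forward-backward (`signal::filtfilt`), so the filter is zero phase and peak
#' positions are not lag-shifted; DC gain is 1.
#'
#' @param rec A [photometry_recording()].
#' @param cutoff Cut-off frequency in Hz; the sampling rate must exceed twice
#'   the cut-off or a configuration error is raised.
#' @param order Filter order (default 2).
#' @return The recording with both channels filtered.
#' @export
pm_lowpass <- function(rec, cutoff = 25, order = 2) {
  stopifnot(inherits(rec, "photometry_recording"))
  fs <- attr(rec, "fs")
  check_number(cutoff, "cutoff", min = 0, strict_min = TRUE)
  if (fs <= 2 * cutoff) {
    rlang::abort(sprintf(
      "Sampling rate (%g Hz) must exceed twice the cut-off (%g Hz).",
      fs, cutoff), class = c("menmod_config_error", "menmod_error"))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- rec
  out$sig470 <- as.numeric(signal::filtfilt(bf, rec$sig470))
  out$iso405 <- as.numeric(signal::filtfilt(bf, rec$iso405))
  restore_pm(out, rec)
}

.exp2_inits <- function(y, t) {
  n <- length(y)
  third <- max(2L, floor(n / 3))
  eps <- max(abs(y)) * 1e-9 + 1e-12
  tail_idx <- (n - third + 1):n
  fit_tail <- try(stats::lm(log(pmax(y[tail_idx], eps)) ~ t[tail_idx]),
                  silent = TRUE)
  if (inherits(fit_tail, "try-error") || anyNA(coef(fit_tail))) {
    c0 <- max(mean(y[tail_idx]), eps); d0 <- -1e-6
  } else {
    d0 <- min(unname(coef(fit_tail)[2]), -1e-9)
    c0 <- max(exp(unname(coef(fit_tail)[1])), eps)
  }
  head_idx <- seq_len(third)
  resid_head <- y[head_idx] - c0 * exp(d0 * t[head_idx])
  fit_head <- try(stats::lm(log(pmax(resid_head, eps)) ~ t[head_idx]),
                  silent = TRUE)
  if (inherits(fit_head, "try-error") || anyNA(coef(fit_head))) {
    a0 <- max(y[1] - c0, eps); b0 <- -1e-3
  } else {
    b0 <- min(unname(coef(fit_head)[2]), -1e-8)
    a0 <- max(exp(unname(coef(fit_head)[1])), eps)
  }
  list(a = a0, b = b0, c = c0, d = d0)
}

#' Fit a photobleaching trend
#'
#' Fits a two-term exponential `a e^{b t} + c e^{d t}` (decay-constrained:
#' `b, d <= 0`) by Levenberg-Marquardt nonlinear least squares. Amplitudes are
#' initialised from the first/last signal values and rate constants from
#' log-linear fits to the first and last thirds. On non-convergence the fit
#' falls back, with a warning, to a single exponential, and as a last resort
#' to the signal mean. For long recordings the trend is fitted on a thinned
#' grid (the bleach curve is smooth) and evaluated at every sample.
#'
#' @param y Channel values (>= 100 samples).
#' @param t Sample times in seconds.
#' @param mask Optional logical vector, `TRUE` for samples to exclude from the
#'   fit (e.g. stimulus-evoked transient support); the fitted curve is still
#'   evaluated everywhere.
#' @param max_fit_points Maximum number of points used in the optimisation.
#' @return An object of class `debleach_fit` with elements `fitted`,
#'   `coefficients`, `model` ("exp2", "exp1" or "const") and `converged`.
#'   Methods: [tidy()], [glance()], `predict()`.
#' @export
fit_debleach <- function(y, t, mask = NULL, max_fit_points = 20000) {
  check_numeric_vec(y, "y")
  check_numeric_vec(t, "t")
  if (length(y) != length(t)) abort_bad_arg("y", "match `t` in length")
  if (length(y) < 100) abort_bad_arg("y", "have at least 100 samples")
  use <- if (is.null(mask)) rep(TRUE, length(y)) else !mask
  yf <- y[use]
  tf <- t[use]
  if (length(yf) > max_fit_points) {
    keep <- seq(1L, length(yf), length.out = max_fit_points)
    yf <- yf[as.integer(keep)]
    tf <- tf[as.integer(keep)]
  }
  inits <- .exp2_inits(yf, tf)
  dat <- data.frame(yy = yf, tt = tf)
  model <- "exp2"
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ a * exp(b * tt) + c * exp(d * tt), data = dat,
      start = inits,
      lower = c(a = 0, b = -Inf, c = 0, d = -Inf),
      upper = c(a = Inf, b = 0, c = Inf, d = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    rlang::warn("Two-term exponential fit did not converge; falling back to a single exponential.")
    model <- "exp1"
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ a * exp(b * tt), data = dat,
        start = list(a = max(mean(yf), 1e-12), b = inits$d),
        lower = c(a = 0, b = -Inf), upper = c(a = Inf, b = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    rlang::warn("Single-exponential fit did not converge; using the signal mean.")
    model <- "const"
    cf <- c(a = mean(yf))
    fitted_all <- rep(mean(yf), length(y))
    converged <- FALSE
  } else {
    cf <- coef(fit)
    fitted_all <- switch(model,
      exp2 = cf[["a"]] * exp(cf[["b"]] * t) + cf[["c"]] * exp(cf[["d"]] * t),
      exp1 = cf[["a"]] * exp(cf[["b"]] * t))
    converged <- TRUE
  }
  structure(
    list(fitted = fitted_all, coefficients = cf, model = model,
         converged = converged, n = length(yf),
         rss = sum((y[use] - fitted_all[use])^2)),
    class = "debleach_fit"
  )
}

#' @export
predict.debleach_fit <- function(object, ...) object$fitted

#' @rdname fit_debleach
#' @param x A `debleach_fit`.
#' @param ... Unused.
#' @method tidy debleach_fit
#' @export
tidy.debleach_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @rdname fit_debleach
#' @method glance debleach_fit
#' @export
glance.debleach_fit <- function(x, ...) {
  tibble(model = x$model, converged = x$converged, n = x$n, rss = x$rss)
}

#' Remove a photobleaching trend from a channel
#'
#' Fits [fit_debleach()] and returns the residual signal (original minus the
#' fitted trend); for a pure double-exponential input the residual is zero to
#' numerical precision.
#'
#' @inheritParams fit_debleach
#' @return Numeric residual vector with the `debleach_fit` attached as
#'   attribute `"fit"`.
#' @export
debleach <- function(y, t, mask = NULL) {
  fit <- fit_debleach(y, t, mask = mask)
  out <- y - fit$fitted
  attr(out, "fit") <- fit
  out
}

#' Isosbestic motion subtraction
#'
#' Elementwise difference between the baseline-corrected calcium channel and
#' the baseline-corrected isosbestic channel. A motion artifact shared by both
#' channels cancels; an artifact present only on the isosbestic channel
#' appears inverted in the output (subtraction semantics).
#'
#' @param corrected_470 Baseline-corrected 470 nm residual.
#' @param corrected_405 Baseline-corrected 405 nm residual, same length.
#' @return Motion-corrected signal.
#' @export
motion_subtract <- function(corrected_470, corrected_405) {
  check_numeric_vec(corrected_470, "corrected_470")
  check_numeric_vec(corrected_405, "corrected_405")
  if (length(corrected_470) != length(corrected_405)) {
    rlang::abort("Channel lengths differ.",
                 class = c("menmod_invalid_input", "menmod_error"))
  }
  corrected_470 - corrected_405
}

#' Run the photometry preprocessing chain on a recording
#'
#' Applies, in fixed order: zero-phase low-pass filtering of both channels;
#' double-exponential debleaching of each channel (samples within
#' `mask_window` seconds after each stimulation onset are masked from the
#' trend fit so evoked transients do not bias it); isosbestic motion
#' subtraction. Because the motion-corrected residual is zero-mean, it is
#' expressed as a fraction of the fitted 470 nm bleach level at each sample
#' and a constant DC level (the mean fitted 470 nm intensity) is restored, so
#' downstream trial segmentation sees a positive baseline and dF/F0 equals the
#' fractional transient amplitude.
#'
#' @param rec A [photometry_recording()].
#' @param cutoff Low-pass cut-off in Hz.
#' @param mask_window Seconds after each onset masked from the bleach fits
#'   (default 60; set to 0 to disable).
#' @return The recording with added columns `sig470_corr`, `iso405_corr`
#'   (debleached residuals), `motion_corrected` (their difference) and
#'   `f_proc` (DC-restored normalised signal used for segmentation); the two
#'   `debleach_fit` objects are in attribute `"fits"`.
#' @export
pm_process <- function(rec, cutoff = 25, mask_window = 60) {
  stopifnot(inherits(rec, "photometry_recording"))
  filt <- pm_lowpass(rec, cutoff = cutoff)
  onsets <- attr(rec, "stim_onsets")
  mask <- rep(FALSE, nrow(filt))
  if (mask_window > 0) {
    for (on in onsets) {
      mask <- mask | (filt$time_s >= on & filt$time_s < on + mask_window)
    }
  }
  fit470 <- fit_debleach(filt$sig470, filt$time_s, mask = mask)
  fit405 <- fit_debleach(filt$iso405, filt$time_s, mask = mask)
  out <- filt
  out$sig470_corr <- filt$sig470 - fit470$fitted
  out$iso405_corr <- filt$iso405 - fit405$fitted
  out$motion_corrected <- motion_subtract(out$sig470_corr, out$iso405_corr)
  level <- mean(fit470$fitted)
  out$f_proc <- level * (1 + out$motion_corrected / fit470$fitted)
  out <- restore_pm(out, rec)
  attr(out, "fits") <- list(sig470 = fit470, iso405 = fit405)
  out
}

#' Segment a signal into per-trial dF/F0 windows
#'
#' For each onset, `F0` is the mean of the signal over `[onset - pre, onset)`
#' and `dF/F0 = (signal - F0) / F0` over `[onset - pre, onset + post)`.
#' Trials whose window exceeds the recording edge are dropped with a warning;
#' trials with `F0 <= 0` are excluded with a warning. Overlap of a trial's
#' window with a previous trial's post-window is allowed and reported via a
#' message.
#'
#' @param signal Numeric signal vector (positive baseline expected).
#' @param time Sample times in seconds, same length.
#' @param onsets Stimulation onsets in seconds.
#' @param pre Pre-stimulation window length in seconds (30 or 15 in the two
#'   fibre configurations).
#' @param post Post-stimulation window length in seconds (150 or 85).
#' @return A tibble of class `trial_segments` with columns `trial`,
#'   `onset_s`, `time_rel_s` (relative to onset), `dff` and `f0`.
#' @export
segment_trials <- function(signal, time, onsets, pre = 30, post = 150) {
  check_numeric_vec(signal, "signal")
  check_numeric_vec(time, "time")
  if (length(signal) != length(time)) abort_bad_arg("signal", "match `time` in length")
  check_numeric_vec(onsets, "onsets")
  check_number(pre, "pre", min = 0, strict_min = TRUE)
  check_number(post, "post", min = 0, strict_min = TRUE)
  onsets <- sort(onsets)
  t0 <- min(time)
  t1 <- max(time)
  fits <- onsets - pre >= t0 - 1e-9 & onsets + post <= t1 + 1e-9
  if (any(!fits)) {
    rlang::warn(sprintf(
      "Dropping %d trial(s) whose window exceeds the recording edge.",
      sum(!fits)))
  }
  onsets <- onsets[fits]
  if (length(onsets) > 1 && any(diff(onsets) < post)) {
    rlang::inform("Some trial windows overlap the previous trial's post-window.")
  }
  segs <- purrr::imap(onsets, function(on, i) {
    idx <- which(time >= on - pre - 1e-9 & time < on + post - 1e-9)
    rel <- time[idx] - on
    f0 <- mean(signal[idx][rel < 0])
    if (!is.finite(f0) || f0 <= 0) {
      rlang::warn(sprintf("Excluding trial %d: non-positive baseline F0.", i))
      return(NULL)
    }
    tibble(trial = i, onset_s = on, time_rel_s = rel,
           dff = (signal[idx] - f0) / f0, f0 = f0)
  })
  out <- bind_rows(segs)
  class(out) <- c("trial_segments", class(tibble()))
  out
}

#' Classify one trial and measure its transient
#'
#' A trial is responsive when its dF/F0 reaches `sigma_k` times the baseline
#' SD (SD of the trial's own pre-window) at any sample within
#' `[0, response_window)` from the onset. The peak intensity and position are
#' the maximum post-onset dF/F0 and its time; the peak width is the interval
#' between the last time before the maximum and the first time after it at
#' which dF/F0 equals half the baseline SD (linear interpolation between
#' samples). If the trace never returns to that level on one side, the width
#' is censored (`NA`, flagged).
#'
#' @param segment One trial's rows from [segment_trials()] (columns
#'   `time_rel_s`, `dff`).
#' @param sigma_k Threshold multiplier on the baseline SD (default 2).
#' @param response_window Classification window in seconds from onset
#'   (default 20).
#' @return A one-row tibble: `responsive`, `sigma`, `peak_intensity`,
#'   `peak_position_s`, `peak_width_s`, `width_censored`.
#' @export
classify_trial <- function(segment, sigma_k = 2, response_window = 20) {
  stopifnot(is.data.frame(segment),
            all(c("time_rel_s", "dff") %in% names(segment)))
  rel <- segment$time_rel_s
  dff <- segment$dff
  sig <- sd(dff[rel < 0])
  in_win <- rel >= 0 & rel < response_window
  responsive <- any(dff[in_win] >= sigma_k * sig)
  post <- which(rel >= 0)
  imax <- post[which.max(dff[post])]
  peak <- dff[imax]
  pos <- rel[imax]
  level <- sig / 2
  cross_left <- NA_real_
  cross_right <- NA_real_
  if (peak <= level) {
    return(tibble(responsive = responsive, sigma = sig, peak_intensity = peak,
                  peak_position_s = pos, peak_width_s = NA_real_,
                  width_censored = TRUE))
  }
  below_left <- which(dff[seq_len(imax)] < level)
  if (length(below_left)) {
    j <- max(below_left) # crossing between j and j+1
    cross_left <- rel[j] + (level - dff[j]) / (dff[j + 1] - dff[j]) *
      (rel[j + 1] - rel[j])
  }
  after <- if (imax < length(dff)) imax + which(dff[(imax + 1):length(dff)] < level) else integer(0)
  if (length(after)) {
    j <- min(after) # crossing between j-1 and j
    cross_right <- rel[j - 1] + (level - dff[j - 1]) / (dff[j] - dff[j - 1]) *
      (rel[j] - rel[j - 1])
  }
  censored <- is.na(cross_left) || is.na(cross_right)
  tibble(
    responsive = responsive,
    sigma = sig,
    peak_intensity = peak,
    peak_position_s = pos,
    peak_width_s = if (censored) NA_real_ else cross_right - cross_left,
    width_censored = censored
  )
}

#' Classify all trials of a segmented session
#'
#' @param segments A `trial_segments` tibble from [segment_trials()].
#' @inheritParams classify_trial
#' @return A tibble with one row per trial (columns of [classify_trial()]
#'   plus `trial`, `onset_s`).
#' @export
classify_trials <- function(segments, sigma_k = 2, response_window = 20) {
  segments |>
    group_by(.data$trial, .data$onset_s) |>
    dplyr::group_modify(~classify_trial(.x, sigma_k = sigma_k,
                                        response_window = response_window)) |>
    ungroup()
}

#' Per-animal spiking probability and pooled summary
#'
#' The fraction of responsive trials in each animal is its spiking
#' probability; across-animal mean and SD are attached as attributes
#' `"mean"` and `"sd"`. Animals without classified trials are excluded with a
#' warning.
#'
#' @param metrics A tibble of per-trial metrics with a logical `responsive`
#'   column and (optionally) an `animal` column; a single-animal table may
#'   omit `animal`.
#' @return A tibble with one row per animal: `animal`, `n_trials`,
#'   `n_responsive`, `spiking_probability`.
#' @examples
#' m <- tibble::tibble(animal = rep(c("m1", "m2"), each = 5),
#'                     responsive = c(rep(TRUE, 5), rep(TRUE, 3), FALSE, FALSE))
#' session_statistics(m)
#' @export
session_statistics <- function(metrics) {
  stopifnot(is.data.frame(metrics), "responsive" %in% names(metrics))
  if (!"animal" %in% names(metrics)) metrics$animal <- "animal_1"
  bad <- is.na(metrics$responsive)
  if (any(bad)) {
    rlang::warn(sprintf("Excluding %d trial(s) with missing classification.", sum(bad)))
    metrics <- metrics[!bad, , drop = FALSE]
  }
  if (nrow(metrics) == 0) {
    rlang::abort("No classified trials.", class = c("menmod_invalid_input", "menmod_error"))
  }
  out <- metrics |>
    group_by(.data$animal) |>
    summarise(n_trials = n(),
              n_responsive = sum(.data$responsive),
              spiking_probability = mean(.data$responsive),
              .groups = "drop")
  attr(out, "mean") <- mean(out$spiking_probability)
  attr(out, "sd") <- if (nrow(out) > 1) sd(out$spiking_probability) else 0
  out
}

#' Full photometry pipeline: filter, debleach, subtract, segment, classify
#'
#' @param rec A [photometry_recording()].
#' @param pre,post Segmentation windows in seconds; preset A is 30/150 s,
#'   preset B 15/85 s.
#' @param sigma_k,response_window Trial classification parameters; see
#'   [classify_trial()].
#' @param cutoff Low-pass cut-off in Hz.
#' @param mask_window Seconds masked from the bleach fit after each onset.
#' @return Per-trial metrics tibble (see [classify_trials()]), with the
#'   processed recording in attribute `"processed"` and the segments in
#'   attribute `"segments"`.
#' @export
analyze_photometry <- function(rec, pre = 30, post = 150, sigma_k = 2,
                               response_window = 20, cutoff = 25,
                               mask_window = 60) {
  proc <- pm_process(rec, cutoff = cutoff, mask_window = mask_window)
  segs <- segment_trials(proc$f_proc, proc$time_s,
                         attr(rec, "stim_onsets"), pre = pre, post = post)
  metrics <- classify_trials(segs, sigma_k = sigma_k,
                             response_window = response_window)
  attr(metrics, "processed") <- proc
  attr(metrics, "segments") <- segs
  metrics
}

#' @method autoplot trial_segments
#' @export
autoplot.trial_segments <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_rel_s, y = .data$dff,
                                       group = .data$trial)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time from stimulation onset (s)",
                  y = expression(Delta * F / F[0]))
}
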