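#' Per-cell fluorescence trace matrix
#'
#' Container for stimulus-locked calcium-imaging traces: a cells-by-frames
#' matrix of raw fluorescence with its frame rate and stimulation schedule.
#' Frame timestamps are `frame_index / fps` with 0-based indexing; all
#' analysis windows are half-open `[start, end)`.
#'
#' @param values Numeric matrix (cells x frames) or a data frame whose first
#'   column is `cell_id` and remaining columns are frames.
#' @param fps Frame rate in frames per second (> 0).
#' @param onsets Strictly increasing stimulation onset times in seconds.
#' @param epoch_duration Stimulation epoch length in seconds (> 0).
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, fps, onsets, epoch_duration) {
  if (is.data.frame(values)) {
    ids <- as.character(values[[1]])
    values <- as.matrix(values[, -1, drop = FALSE])
    rownames(values) <- ids
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_bad_arg("values", "be a numeric matrix or a data frame with a cell_id column")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cell_%03d", seq_len(nrow(values)))
  }
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  check_numeric_vec(onsets, "onsets")
  if (length(onsets) < 1 || any(diff(onsets) <= 0)) {
    abort_bad_arg("onsets", "be a strictly increasing vector with at least one onset")
  }
  check_number(epoch_duration, "epoch_duration", min = 0, strict_min = TRUE)
  n_frames <- ncol(values)
  if (max(onsets) >= n_frames / fps) {
    abort_bad_arg("onsets", "lie within the recording")
  }
  structure(
    list(values = values, fps = fps, onsets = onsets,
         epoch_duration = epoch_duration),
    class = "trace_matrix"
  )
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d cells x %d frames at %g fps; %d epochs (%g s) at t = %s s\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$fps,
              length(x$onsets), x$epoch_duration,
              paste(format(x$onsets), collapse = ", ")))
  invisible(x)
}

#' @export
print.dff_matrix <- print.trace_matrix

frame_times <- function(x) (seq_len(ncol(x$values)) - 1) / x$fps

#' Analysis configuration for calcium-event statistics
#'
#' @param baseline_window Baseline length in seconds before the first onset
#'   used for F0 and the baseline SD (default 30).
#' @param response_window Post-onset window in seconds in which a response
#'   must occur (default 15).
#' @param response_k Multiplier on the baseline SD for the per-cell
#'   responsiveness rule (default 3).
#' @param peak_threshold_factor Multiplier on the reference SD for peak
#'   counting (default 0.5).
#' @param spike_k Multiplier on the baseline SD of the population-average
#'   trace for the epoch spiking rule (default 3).
#' @param sigma_scope Scope of the baseline SD in the responsiveness rule:
#'   `"pooled"` (default; the mean of per-cell baseline SDs across the video)
#'   or `"per_cell"`. With only ~30 baseline frames at 1 fps the per-cell
#'   estimate roughly doubles the rule's false-positive rate, so the pooled
#'   video-level estimate is the default.
#' @param peak_sd_scope Scope of the SD used for the peak-counting threshold:
#'   `"pooled"` (default; per-cell SD over the full recording averaged across
#'   cells) or `"per_cell"`.
#' @return An object of class `calcium_config`.
#' @export
calcium_config <- function(baseline_window = 30, response_window = 15,
                           response_k = 3, peak_threshold_factor = 0.5,
                           spike_k = 3,
                           sigma_scope = c("pooled", "per_cell"),
                           peak_sd_scope = c("pooled", "per_cell")) {
  check_number(baseline_window, "baseline_window", min = 0, strict_min = TRUE)
  check_number(response_window, "response_window", min = 0, strict_min = TRUE)
  check_number(response_k, "response_k", min = 0)
  check_number(peak_threshold_factor, "peak_threshold_factor", min = 0)
  check_number(spike_k, "spike_k", min = 0)
  structure(
    list(baseline_window = baseline_window,
         response_window = response_window,
         response_k = response_k,
         peak_threshold_factor = peak_threshold_factor,
         spike_k = spike_k,
         sigma_scope = match.arg(sigma_scope),
         peak_sd_scope = match.arg(peak_sd_scope)),
    class = "calcium_config"
  )
}

baseline_frames <- function(traces, config) {
  tt <- frame_times(traces)
  first <- traces$onsets[1]
  idx <- which(tt >= first - config$baseline_window & tt < first)
  if (first - config$baseline_window < -1e-9 || length(idx) == 0) {
    rlang::abort(sprintf(
      "Baseline window (%g s) does not fit before the first onset (%g s).",
      config$baseline_window, first),
      class = c("menmod_config_error", "menmod_error"))
  }
  idx
}

#' Relative fluorescence change (dF/F0)
#'
#' Per cell, `F0` is the mean raw fluorescence over the baseline window
#' immediately preceding the first stimulation onset, and
#' `dF/F0 = (F - F0) / F0` for every frame. Cells with non-positive `F0` are
#' excluded with a warning (their ids are kept in the `"excluded"` attribute).
#'
#' @param traces A [trace_matrix()].
#' @param config A [calcium_config()].
#' @return A `dff_matrix` (same container shape as the input) whose `values`
#'   are dF/F0, with per-cell `f0` and `baseline_sd` stored alongside.
#' @export
compute_dff <- function(traces, config = calcium_config()) {
  stopifnot(inherits(traces, "trace_matrix"))
  bidx <- baseline_frames(traces, config)
  f0 <- rowMeans(traces$values[, bidx, drop = FALSE])
  bad <- f0 <= 0
  if (any(bad)) {
    rlang::warn(sprintf(
      "Excluding %d cell(s) with non-positive baseline F0: %s",
      sum(bad), paste(rownames(traces$values)[bad], collapse = ", ")))
  }
  vals <- traces$values[!bad, , drop = FALSE]
  f0k <- f0[!bad]
  dff <- sweep(sweep(vals, 1, f0k, "-"), 1, f0k, "/")
  out <- structure(
    list(values = dff, fps = traces$fps, onsets = traces$onsets,
         epoch_duration = traces$epoch_duration,
         f0 = f0k,
         baseline_idx = bidx,
         baseline_sd = apply(dff[, bidx, drop = FALSE], 1, sd)),
    class = c("dff_matrix", "trace_matrix")
  )
  attr(out, "excluded") <- rownames(traces$values)[bad]
  out
}

# local maxima of a vector: strictly greater than both neighbouring distinct
# values; plateaus count once, at their first frame; endpoints are not peaks
find_local_maxima <- function(x) {
  r <- rle(x)
  v <- r$values
  n <- length(v)
  if (n < 3) return(integer(0))
  starts <- cumsum(c(1, r$lengths[-n]))
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n], FALSE)
  starts[is_peak]
}

#' Count fluorescence peaks per cell
#'
#' Local maxima of dF/F0 (strictly greater than both neighbours, plateaus
#' resolved to their first frame) whose height above the cell's baseline mean
#' exceeds `peak_threshold_factor` times a reference SD: by default half the
#' mean, across cells, of each cell's dF/F0 SD over the full recording.
#'
#' @param dff A `dff_matrix` from [compute_dff()].
#' @param config A [calcium_config()].
#' @return A tibble with columns `cell_id` and `n_peaks`.
#' @export
count_peaks <- function(dff, config = calcium_config()) {
  stopifnot(inherits(dff, "dff_matrix"))
  full_sd <- apply(dff$values, 1, sd)
  ref_sd <- switch(config$peak_sd_scope,
                   pooled = rep(mean(full_sd), length(full_sd)),
                   per_cell = full_sd)
  thr <- config$peak_threshold_factor * ref_sd
  base_mean <- rowMeans(dff$values[, dff$baseline_idx, drop = FALSE])
  counts <- vapply(seq_len(nrow(dff$values)), function(i) {
    x <- dff$values[i, ]
    pk <- find_local_maxima(x)
    sum(x[pk] - base_mean[i] > thr[i])
  }, integer(1))
  tibble(cell_id = rownames(dff$values), n_peaks = counts)
}

response_windows <- function(dff, config) {
  tt <- frame_times(dff)
  n_frames <- ncol(dff$values)
  lapply(dff$onsets, function(on) {
    idx <- which(tt >= on & tt < on + config$response_window)
    if (length(idx) == 0) {
      rlang::abort(sprintf("Response window at onset %g s has no frames.", on),
                   class = c("menmod_config_error", "menmod_error"))
    }
    if (on + config$response_window > n_frames / dff$fps + 1e-9) {
      rlang::warn(sprintf(
        "Response window for onset %g s is clipped by the end of the recording.", on))
    }
    idx
  })
}

#' Classify cells as responsive per stimulation epoch
#'
#' A cell is responsive to an epoch when its dF/F0 exceeds
#' `response_k` times the baseline SD at any frame within
#' `[onset, onset + response_window)`. Cells with zero baseline variance are
#' excluded with a warning.
#'
#' @inheritParams count_peaks
#' @return A tibble with columns `cell_id`, `epoch`, `onset_s`, `responsive`.
#' @seealso [responsiveness()] for the per-epoch responsive fraction.
#' @export
classify_responsive <- function(dff, config = calcium_config()) {
  stopifnot(inherits(dff, "dff_matrix"))
  zero_var <- dff$baseline_sd == 0
  if (any(zero_var)) {
    rlang::warn(sprintf(
      "Excluding %d cell(s) with zero baseline variance: %s",
      sum(zero_var), paste(rownames(dff$values)[zero_var], collapse = ", ")))
  }
  keep <- !zero_var
  sig <- dff$baseline_sd[keep]
  if (config$sigma_scope == "pooled") sig[] <- mean(sig)
  wins <- response_windows(dff, config)
  purrr::imap_dfr(wins, function(idx, ep) {
    sub <- dff$values[keep, idx, drop = FALSE]
    hit <- apply(sub > config$response_k * sig, 1, any)
    tibble(cell_id = rownames(dff$values)[keep],
           epoch = ep,
           onset_s = dff$onsets[ep],
           responsive = unname(hit))
  })
}

#' Responsive fraction per stimulation epoch
#'
#' @inheritParams count_peaks
#' @return A tibble with columns `epoch`, `onset_s`, `n_cells`,
#'   `responsiveness` (responsive fraction in `[0, 1]`).
#' @export
responsiveness <- function(dff, config = calcium_config()) {
  classify_responsive(dff, config) |>
    group_by(.data$epoch, .data$onset_s) |>
    summarise(n_cells = n(),
              responsiveness = mean(.data$responsive),
              .groups = "drop")
}

#' Spiking probability of the population-average trace
#'
#' The population-average dF/F0 trace is computed per frame; an epoch
#' "spikes" when the average exceeds `spike_k` times the SD of the average
#' trace over the baseline window, at any frame of the epoch's response
#' window. The spiking probability is the fraction of spiking epochs.
#'
#' @inheritParams count_peaks
#' @return A single numeric probability, with the per-epoch logical vector in
#'   attribute `"epochs"`.
#' @export
spiking_probability <- function(dff, config = calcium_config()) {
  stopifnot(inherits(dff, "dff_matrix"))
  if (length(dff$onsets) < 1) {
    rlang::abort("At least one stimulation epoch is required.",
                 class = c("menmod_invalid_input", "menmod_error"))
  }
  avg <- colMeans(dff$values)
  sig <- sd(avg[dff$baseline_idx])
  wins <- response_windows(dff, config)
  spiked <- vapply(wins, function(idx) any(avg[idx] > config$spike_k * sig),
                   logical(1))
  out <- mean(spiked)
  attr(out, "epochs") <- spiked
  out
}

#' Stimulus-to-peak latency of responsive cells
#'
#' For each responsive (cell, epoch) pair, the latency is the time from the
#' stimulation onset to the frame of maximal dF/F0 within the response
#' window (earliest frame on ties), reported in seconds at frame resolution.
#' Non-responsive pairs are absent from the result, not zero.
#'
#' @inheritParams count_peaks
#' @return A tibble with columns `cell_id`, `epoch`, `onset_s`, `latency_s`,
#'   `peak_time_s`, `peak_amplitude`.
#' @export
response_latency <- function(dff, config = calcium_config()) {
  stopifnot(inherits(dff, "dff_matrix"))
  flags <- classify_responsive(dff, config)
  wins <- response_windows(dff, config)
  tt <- frame_times(dff)
  resp <- flags[flags$responsive, , drop = FALSE]
  if (nrow(resp) == 0) {
    return(tibble(cell_id = character(), epoch = integer(),
                  onset_s = numeric(), latency_s = numeric(),
                  peak_time_s = numeric(), peak_amplitude = numeric()))
  }
  rows <- purrr::pmap_dfr(resp[c("cell_id", "epoch", "onset_s")],
    function(cell_id, epoch, onset_s) {
      idx <- wins[[epoch]]
      x <- dff$values[cell_id, idx]
      j <- idx[which.max(x)]
      tibble(cell_id = cell_id, epoch = epoch, onset_s = onset_s,
             latency_s = tt[j] - onset_s,
             peak_time_s = tt[j],
             peak_amplitude = dff$values[cell_id, j])
    })
  arrange(rows, .data$epoch, .data$cell_id)
}

#' Per-cell, per-epoch event table
#'
#' Joins responsiveness flags, latency/peak statistics and per-cell peak
#' counts into the long event table used for reporting.
#'
#' @param traces A [trace_matrix()] of raw fluorescence.
#' @param config A [calcium_config()].
#' @return A tibble with one row per (cell, epoch): `cell_id`, `epoch`,
#'   `onset_s`, `responsive`, `latency_s`, `peak_time_s`, `peak_amplitude`
#'   (all `NA` when not responsive) and the per-cell `n_peaks`.
#' @export
calcium_events <- function(traces, config = calcium_config()) {
  dff <- compute_dff(traces, config)
  flags <- classify_responsive(dff, config)
  lat <- response_latency(dff, config)
  pk <- count_peaks(dff, config)
  flags |>
    left_join(lat, by = c("cell_id", "epoch", "onset_s")) |>
    left_join(pk, by = "cell_id") |>
    arrange(.data$epoch, .data$cell_id)
}

#' One-row summary of a calcium-imaging video
#'
#' @inheritParams calcium_events
#' @return A tibble with the mean responsiveness across epochs, the spiking
#'   probability, latency mean/SD over responsive pairs, and cell counts.
#' @export
calcium_summary <- function(traces, config = calcium_config()) {
  dff <- compute_dff(traces, config)
  resp <- responsiveness(dff, config)
  lat <- response_latency(dff, config)
  sp <- spiking_probability(dff, config)
  tibble(
    n_cells = nrow(dff$values),
    n_excluded = length(attr(dff, "excluded")),
    n_epochs = length(dff$onsets),
    responsiveness_mean = mean(resp$responsiveness),
    spiking_probability = as.numeric(sp),
    latency_mean_s = if (nrow(lat)) mean(lat$latency_s) else NA_real_,
    latency_sd_s = if (nrow(lat) > 1) sd(lat$latency_s) else NA_real_
  )
}

#' Plot dF/F0 traces with the stimulation schedule
#'
#' @param object A `dff_matrix` from [compute_dff()].
#' @param cells Optional character vector of cell ids to show (default: up to
#'   20 cells).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dff_matrix
#' @export
autoplot.dff_matrix <- function(object, cells = NULL, ...) {
  ids <- cells %||% utils::head(rownames(object$values), 20)
  tt <- frame_times(object)
  df <- as_tibble(t(object$values[ids, , drop = FALSE]))
  df$time_s <- tt
  long <- tidyr::pivot_longer(df, -"time_s", names_to = "cell_id",
                              values_to = "dff")
  stim <- tibble(xmin = object$onsets,
                 xmax = object$onsets + object$epoch_duration)
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(data = stim,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf),
                       alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(x = .data$time_s, y = .data$dff),
                       linewidth = 0.3) +
    ggplot2::facet_wrap(~cell_id) +
    ggplot2::labs(x = "Time (s)", y = expression(Delta * F / F[0]))
}
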