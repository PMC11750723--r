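# seed handling: generators are deterministic under config$seed without
# clobbering the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Truncated-normal parameters matching observed moments
#'
#' Solves for the location and scale of a normal distribution truncated below
#' at `lower` so that the truncated distribution has the requested mean and
#' SD. Reported latency statistics are sample moments of necessarily
#' non-negative values, so a generator that plants latencies must
#' moment-match the truncated distribution rather than truncate a normal with
#' those moments (which would inflate the mean).
#'
#' @param mean,sd Target mean and SD of the truncated distribution
#'   (`mean > lower`, `sd > 0`). The coefficient of variation
#'   `sd / (mean - lower)` must be below 1 (the truncated-normal limit).
#' @param lower Truncation bound (default 0).
#' @return A list with elements `mu` and `sigma` of the underlying normal.
#' @export
truncnorm_moment_params <- function(mean, sd, lower = 0) {
  check_number(mean, "mean")
  check_number(sd, "sd", min = 0, strict_min = TRUE)
  if (mean <= lower) abort_bad_arg("mean", "exceed the truncation bound")
  m <- mean - lower
  cv <- sd / m
  if (cv >= 1) {
    abort_bad_arg("sd", "give a coefficient of variation below 1 (truncated-normal limit)")
  }
  if (cv < 0.05) {
    # truncation negligible at > 20 sigma from the bound
    return(list(mu = mean, sigma = sd))
  }
  hazard <- function(a) exp(dnorm(a, log = TRUE) -
                              pnorm(a, lower.tail = FALSE, log.p = TRUE))
  cv_of <- function(a) {
    h <- hazard(a)
    v <- 1 + a * h - h^2
    sqrt(pmax(v, 0)) / (h - a)
  }
  root <- uniroot(function(a) cv_of(a) - cv, lower = -35, upper = 8,
                  tol = 1e-12)
  a <- root$root
  h <- hazard(a)
  sigma <- sd / sqrt(1 + a * h - h^2)
  list(mu = lower - a * sigma, sigma = sigma)
}

# draw from a normal truncated to [lower, upper] by inversion
rtruncnorm_range <- function(n, mu, sigma, lower = 0, upper = Inf) {
  plo <- pnorm(lower, mu, sigma)
  phi <- pnorm(upper, mu, sigma)
  qnorm(runif(n, plo, phi), mu, sigma)
}

# difference-of-exponentials kernel normalised to unit peak
dexp_kernel <- function(tau, rise, decay) {
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  knorm <- exp(-tp / decay) - exp(-tp / rise)
  out <- numeric(length(tau))
  pos <- tau >= 0
  out[pos] <- (exp(-tau[pos] / decay) - exp(-tau[pos] / rise)) / knorm
  out
}

kernel_peak_time <- function(rise, decay) {
  rise * decay / (decay - rise) * log(decay / rise)
}

#' Configuration of the synthetic calcium-imaging generator
#'
#' Defines the statistical structure of a stimulus-locked calcium-imaging
#' video: per-epoch Bernoulli cell responses, a truncated-normal
#' stimulus-to-peak latency distribution (moment-matched, see
#' [truncnorm_moment_params()]), a difference-of-exponentials indicator
#' kernel, multiplicative baseline and additive white noise. Planted
#' latencies are quantised to the frame grid so the ground-truth fluorescence
#' maximum is representable in the sampled trace.
#'
#' @param n_cells Number of cells.
#' @param fps Frame rate (frames per second).
#' @param n_epochs Number of stimulation epochs.
#' @param epoch_duration Epoch length in seconds.
#' @param inter_epoch Rest interval between epochs in seconds.
#' @param first_onset Time of the first onset (>= 30 s so the baseline window
#'   fits).
#' @param p_response Per-cell, per-epoch response probability.
#' @param latency_mean,latency_sd Target mean/SD (s) of planted latencies.
#' @param latency_max Upper bound (s) on planted latencies (response-window
#'   length used by the matching analysis).
#' @param kernel_rise,kernel_decay Indicator kernel time constants in seconds
#'   (defaults emulate a slow genetically encoded calcium indicator).
#' @param amplitude Mean transient amplitude in dF/F0 units.
#' @param amplitude_cv Lognormal coefficient of variation of amplitudes.
#' @param noise_sd White-noise SD in dF/F0 units.
#' @param spontaneous_rate Spontaneous event rate per cell (events per
#'   second; default 0).
#' @param baseline_f0 Baseline fluorescence level (a.u.).
#' @param tail Recording tail after the last response window (s).
#' @param seed Integer seed fixing the dataset exactly (`NULL` to use the
#'   current RNG state).
#' @return An object of class `calcium_sim_config`.
#' @seealso [calcium_preset()] for named presets, [gen_calcium_dataset()].
#' @export
calcium_sim_config <- function(n_cells = 300, fps = 1, n_epochs = 5,
                               epoch_duration = 2, inter_epoch = 30,
                               first_onset = 30, p_response = 0.741,
                               latency_mean = 3.9, latency_sd = 2.9,
                               latency_max = 15,
                               kernel_rise = 0.2, kernel_decay = 1.5,
                               amplitude = 0.5, amplitude_cv = 0.2,
                               noise_sd = 0.05, spontaneous_rate = 0,
                               baseline_f0 = 100, tail = 10, seed = NULL) {
  check_number(n_cells, "n_cells", min = 1)
  check_number(fps, "fps", min = 0, strict_min = TRUE)
  check_number(n_epochs, "n_epochs", min = 1)
  check_number(p_response, "p_response", min = 0, max = 1)
  check_number(latency_mean, "latency_mean", min = 0, strict_min = TRUE)
  check_number(latency_sd, "latency_sd", min = 0, strict_min = TRUE)
  check_number(latency_max, "latency_max", min = 0, strict_min = TRUE)
  check_number(kernel_rise, "kernel_rise", min = 0, strict_min = TRUE)
  check_number(kernel_decay, "kernel_decay", min = kernel_rise,
               strict_min = TRUE)
  check_number(amplitude, "amplitude", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(spontaneous_rate, "spontaneous_rate", min = 0)
  check_number(baseline_f0, "baseline_f0", min = 0, strict_min = TRUE)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(n_cells = as.integer(n_cells), fps = fps,
         n_epochs = as.integer(n_epochs), epoch_duration = epoch_duration,
         inter_epoch = inter_epoch, first_onset = first_onset,
         p_response = p_response, latency_mean = latency_mean,
         latency_sd = latency_sd, latency_max = latency_max,
         kernel_rise = kernel_rise, kernel_decay = kernel_decay,
         amplitude = amplitude, amplitude_cv = amplitude_cv,
         noise_sd = noise_sd, spontaneous_rate = spontaneous_rate,
         baseline_f0 = baseline_f0, tail = tail, seed = seed),
    class = "calcium_sim_config"
  )
}

#' Named presets of the calcium generator
#'
#' The three in-vitro presets correspond to particle surface densities of
#' 0.75, 0.5 and 0.25 ug mm^-2, with response probabilities 0.741, 0.463 and
#' 0.276 and the 3.9 +/- 2.9 s latency distribution measured at 1 fps. The
#' `"fast-10fps"` preset emulates fast-kinetics imaging at 10 fps (857 +/-
#' 69 ms planted latency, fast indicator kernel, 3 s response window); its
#' matching analysis settings are attached as attribute `"analysis_config"`.
#'
#' @param name Preset name.
#' @param seed Optional seed stored in the config.
#' @return A [calcium_sim_config()].
#' @export
calcium_preset <- function(name = c("invitro-0.75", "invitro-0.5",
                                    "invitro-0.25", "fast-10fps"),
                           seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    "invitro-0.75" = calcium_sim_config(p_response = 0.741, seed = seed),
    "invitro-0.5" = calcium_sim_config(p_response = 0.463, seed = seed),
    "invitro-0.25" = calcium_sim_config(p_response = 0.276, seed = seed),
    "fast-10fps" = calcium_sim_config(
      n_cells = 100, fps = 10, n_epochs = 5, epoch_duration = 2,
      inter_epoch = 20, p_response = 0.95,
      latency_mean = 0.857, latency_sd = 0.069, latency_max = 3,
      kernel_rise = 0.05, kernel_decay = 0.4,
      amplitude = 0.5, noise_sd = 0.02, seed = seed)
  )
  attr(cfg, "preset") <- name
  attr(cfg, "analysis_config") <- if (name == "fast-10fps") {
    calcium_config(response_window = 3)
  } else {
    calcium_config()
  }
  cfg
}

#' Generate a synthetic calcium-imaging dataset with ground truth
#'
#' Per cell and epoch, a response is drawn as Bernoulli(`p_response`); a
#' responding pair receives one transient whose fluorescence maximum lands at
#' `onset + latency`, with the latency drawn from the moment-matched
#' truncated normal and quantised to the frame grid. The trace is
#' `baseline_f0 * (1 + sum of kernels) + baseline_f0 * noise`, clipped at a
#' small positive floor. Identical configs with the same seed give
#' bit-identical datasets.
#'
#' @param config A [calcium_sim_config()].
#' @return A list with `traces` (a [trace_matrix()]) and `truth` (list with
#'   the `responded` cells-by-epochs matrix, an `events` tibble of planted
#'   latencies/amplitudes, the onsets and the config).
#' @export
gen_calcium_dataset <- function(config = calcium_sim_config()) {
  stopifnot(inherits(config, "calcium_sim_config"))
  with_local_seed(config$seed, {
    fps <- config$fps
    onsets <- config$first_onset +
      (seq_len(config$n_epochs) - 1) * (config$epoch_duration + config$inter_epoch)
    duration <- max(onsets) + config$latency_max + config$tail
    n_frames <- ceiling(duration * fps)
    if (max(onsets) + config$latency_max > n_frames / fps) {
      rlang::abort("Epoch windows overlap the recording end.",
                   class = c("menmod_config_error", "menmod_error"))
    }
    tt <- (seq_len(n_frames) - 1) / fps
    tn <- truncnorm_moment_params(config$latency_mean, config$latency_sd)
    tp <- kernel_peak_time(config$kernel_rise, config$kernel_decay)

    responded <- matrix(
      runif(config$n_cells * config$n_epochs) < config$p_response,
      nrow = config$n_cells, ncol = config$n_epochs)
    cell_ids <- sprintf("cell_%03d", seq_len(config$n_cells))
    rownames(responded) <- cell_ids

    sig <- matrix(0, nrow = config$n_cells, ncol = n_frames)
    events <- list()
    for (ep in seq_len(config$n_epochs)) {
      idx <- which(responded[, ep])
      if (!length(idx)) next
      lat <- rtruncnorm_range(length(idx), tn$mu, tn$sigma,
                              lower = 0, upper = config$latency_max)
      lat_q <- pmin(pmax(round(lat * fps) / fps, 0),
                    config$latency_max - 1 / fps)
      amp <- config$amplitude *
        exp(rnorm(length(idx), 0, config$amplitude_cv) -
              config$amplitude_cv^2 / 2)
      peak_t <- onsets[ep] + lat_q
      for (j in seq_along(idx)) {
        sig[idx[j], ] <- sig[idx[j], ] +
          amp[j] * dexp_kernel(tt - (peak_t[j] - tp),
                               config$kernel_rise, config$kernel_decay)
      }
      events[[ep]] <- tibble(
        cell_id = cell_ids[idx], epoch = ep, onset_s = onsets[ep],
        latency_s = lat_q, latency_raw_s = lat, amplitude = amp,
        peak_time_s = peak_t)
    }
    if (config$spontaneous_rate > 0) {
      n_sp <- stats::rpois(config$n_cells, config$spontaneous_rate * duration)
      for (i in which(n_sp > 0)) {
        st <- runif(n_sp[i], 0, duration)
        amp <- config$amplitude *
          exp(rnorm(n_sp[i], 0, config$amplitude_cv) - config$amplitude_cv^2 / 2)
        for (j in seq_len(n_sp[i])) {
          sig[i, ] <- sig[i, ] +
            amp[j] * dexp_kernel(tt - st[j], config$kernel_rise,
                                 config$kernel_decay)
        }
      }
    }
    noise <- matrix(rnorm(length(sig), 0, config$noise_sd), nrow = nrow(sig))
    values <- config$baseline_f0 * (1 + sig + noise)
    floor_level <- 0.01 * config$baseline_f0
    n_clip <- sum(values < floor_level)
    if (n_clip > 0) {
      rlang::inform(sprintf("Clipped %d sample(s) at the positive floor.", n_clip))
      values[values < floor_level] <- floor_level
    }
    rownames(values) <- cell_ids
    list(
      traces = trace_matrix(values, fps = fps, onsets = onsets,
                            epoch_duration = config$epoch_duration),
      truth = list(responded = responded,
                   events = bind_rows(events),
                   onsets = onsets,
                   config = config)
    )
  })
}

#' Configuration of the synthetic fibre-photometry generator
#'
#' Emulates a two-channel photometry session: per-channel two-term
#' exponential photobleaching, a motion artifact shared identically
#' (multiplicatively) by both channels, stimulus-locked fast primary and slow
#' secondary (~80 s decay) transients on the calcium channel only, Bernoulli
#' per-trial responsiveness, a slow calcium-channel-only fluctuation
#' (spontaneous/hemodynamic activity, the component that survives isosbestic
#' subtraction and sets the baseline SD of real recordings) and white sensor
#' noise.
#'
#' @param n_trials Number of stimulation trials.
#' @param fs Sampling rate in Hz (> 50, filter precondition).
#' @param inter_trial Trial spacing in seconds.
#' @param first_onset First onset time in seconds (a pre-stimulus baseline of
#'   several minutes is typical to absorb fast bleaching).
#' @param stim_duration Stimulation epoch length in seconds.
#' @param p_trial Per-trial response probability.
#' @param primary_amplitude Primary transient amplitude (dF/F0 units).
#' @param primary_rise,primary_decay Primary transient time constants (s).
#' @param latency_mean,latency_sd Normal distribution of the primary-peak
#'   latency from onset (s).
#' @param secondary_amplitude,secondary_rise,secondary_decay Slow secondary
#'   transient parameters (s); set `secondary_amplitude = 0` to disable.
#' @param bleach470,bleach405 Named lists `list(a1, tau1, a2, tau2)` of the
#'   two-term bleach curves `a1 e^{-t/tau1} + a2 e^{-t/tau2}` (a.u.).
#' @param motion_sd Shared multiplicative motion-artifact SD (band-limited
#'   below `motion_cutoff` Hz).
#' @param motion_cutoff Motion bandwidth in Hz.
#' @param slow_sd SD of the quasi-periodic physiological baseline fluctuation
#'   on the calcium channel (dF/F0 units). Modelled as a random-phase
#'   oscillation (vasomotion under anaesthesia), i.e. bounded at
#'   `sqrt(2) * slow_sd`: the regime in which a 2-sigma any-sample rule is
#'   informative. A Gaussian slow process of any correlation time makes that
#'   rule's false-positive rate approach one over a 20 s window.
#' @param slow_freq Frequency of the physiological oscillation (Hz).
#' @param noise_sd White sensor-noise SD (relative units, per channel).
#' @param tail Recording tail after the last post-window (s).
#' @param seed Integer seed (`NULL` for current RNG state).
#' @return An object of class `photometry_sim_config`.
#' @seealso [photometry_preset()], [gen_photometry_session()].
#' @export
photometry_sim_config <- function(n_trials = 20, fs = 130, inter_trial = 180,
                                  first_onset = 330, stim_duration = 5,
                                  p_trial = 0.791,
                                  primary_amplitude = 0.05,
                                  primary_rise = 1, primary_decay = 8,
                                  latency_mean = 2, latency_sd = 0.5,
                                  secondary_amplitude = 0.015,
                                  secondary_rise = 5, secondary_decay = 80,
                                  bleach470 = list(a1 = 20, tau1 = 180,
                                                   a2 = 80, tau2 = 5000),
                                  bleach405 = list(a1 = 19, tau1 = 180,
                                                   a2 = 76, tau2 = 5000),
                                  motion_sd = 0.01, motion_cutoff = 5,
                                  slow_sd = 0.01, slow_freq = 0.25,
                                  noise_sd = 0.0015, tail = 10, seed = NULL) {
  check_number(n_trials, "n_trials", min = 1)
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  if (fs <= 50) {
    rlang::abort("fs must exceed 50 Hz (25 Hz low-pass precondition).",
                 class = c("menmod_config_error", "menmod_error"))
  }
  check_number(p_trial, "p_trial", min = 0, max = 1)
  check_number(first_onset, "first_onset", min = 30)
  structure(
    list(n_trials = as.integer(n_trials), fs = fs, inter_trial = inter_trial,
         first_onset = first_onset, stim_duration = stim_duration,
         p_trial = p_trial, primary_amplitude = primary_amplitude,
         primary_rise = primary_rise, primary_decay = primary_decay,
         latency_mean = latency_mean, latency_sd = latency_sd,
         secondary_amplitude = secondary_amplitude,
         secondary_rise = secondary_rise, secondary_decay = secondary_decay,
         bleach470 = bleach470, bleach405 = bleach405,
         motion_sd = motion_sd, motion_cutoff = motion_cutoff,
         slow_sd = slow_sd, slow_freq = slow_freq, noise_sd = noise_sd,
         tail = tail, seed = seed),
    class = "photometry_sim_config"
  )
}

#' Named presets of the photometry generator
#'
#' `"vta-100hz"`: 5 s stimulation epochs, per-trial response probability
#' 0.791. `"vta-150hz"`: 2 s epochs, probability 0.659. Both use the 30/150 s
#' segmentation windows (attached as attribute `"analysis"`).
#'
#' @param name Preset name.
#' @param seed Optional seed stored in the config.
#' @return A [photometry_sim_config()].
#' @export
photometry_preset <- function(name = c("vta-100hz", "vta-150hz"),
                              seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    "vta-100hz" = photometry_sim_config(stim_duration = 5, p_trial = 0.791,
                                        seed = seed),
    "vta-150hz" = photometry_sim_config(stim_duration = 2, p_trial = 0.659,
                                        seed = seed)
  )
  attr(cfg, "preset") <- name
  attr(cfg, "analysis") <- list(pre = 30, post = 150)
  cfg
}

# band-limited Gaussian noise: zero-phase low-passed white noise rescaled to
# the requested SD
bandlimited_noise <- function(n, fs, cutoff, sd_target) {
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  x <- as.numeric(signal::filtfilt(bf, rnorm(n)))
  x / sd(x) * sd_target
}

# bounded quasi-periodic baseline fluctuation: random-phase oscillation with
# marginal SD sd_target (maximum sqrt(2) * sd_target)
physio_oscillation <- function(tt, freq, sd_target) {
  sd_target * sqrt(2) * sin(2 * pi * freq * tt + runif(1, 0, 2 * pi))
}

#' Generate a synthetic fibre-photometry session with ground truth
#'
#' The calcium channel is
#' `bleach470(t) * (1 + transients + physio + motion + noise)` and the
#' isosbestic channel `bleach405(t) * (1 + motion + noise)`, with the motion
#' artifact realization identical on both channels and transients (primary +
#' slow secondary) plus the bounded physiological oscillation on the calcium
#' channel only. Deterministic under the config seed.
#'
#' @param config A [photometry_sim_config()].
#' @return A list with `recording` (a [photometry_recording()]) and `truth`
#'   (per-trial tibble with responded flags, planted peak latencies and
#'   amplitudes; the motion and slow-noise traces; the config).
#' @export
gen_photometry_session <- function(config = photometry_sim_config()) {
  stopifnot(inherits(config, "photometry_sim_config"))
  with_local_seed(config$seed, {
    fs <- config$fs
    onsets <- config$first_onset +
      (seq_len(config$n_trials) - 1) * config$inter_trial
    duration <- max(onsets) + 150 + config$tail
    n <- ceiling(duration * fs) + 1
    tt <- (seq_len(n) - 1) / fs
    bl <- function(p) p$a1 * exp(-tt / p$tau1) + p$a2 * exp(-tt / p$tau2)
    b470 <- bl(config$bleach470)
    b405 <- bl(config$bleach405)

    responded <- runif(config$n_trials) < config$p_trial
    lat <- rnorm(config$n_trials, config$latency_mean, config$latency_sd)
    lat <- pmax(lat, 0.1)
    amp <- config$primary_amplitude *
      exp(rnorm(config$n_trials, 0, 0.1) - 0.005)
    tp1 <- kernel_peak_time(config$primary_rise, config$primary_decay)
    transients <- numeric(n)
    for (i in which(responded)) {
      start <- onsets[i] + lat[i] - tp1
      transients <- transients +
        amp[i] * dexp_kernel(tt - start, config$primary_rise,
                             config$primary_decay)
      if (config$secondary_amplitude > 0) {
        transients <- transients +
          config$secondary_amplitude *
          dexp_kernel(tt - (onsets[i] + lat[i]),
                      config$secondary_rise, config$secondary_decay)
      }
    }
    motion <- bandlimited_noise(n, fs, config$motion_cutoff, config$motion_sd)
    slow <- physio_oscillation(tt, config$slow_freq, config$slow_sd)
    sig470 <- b470 * (1 + transients + slow + motion +
                        rnorm(n, 0, config$noise_sd))
    iso405 <- b405 * (1 + motion + rnorm(n, 0, config$noise_sd))
    floor_level <- 1e-3
    sig470 <- pmax(sig470, floor_level)
    iso405 <- pmax(iso405, floor_level)

    rec <- photometry_recording(time_s = tt, sig470 = sig470,
                                iso405 = iso405, fs = fs,
                                stim_onsets = onsets,
                                stim_duration = config$stim_duration)
    list(
      recording = rec,
      truth = list(
        trials = tibble(trial = seq_len(config$n_trials), onset_s = onsets,
                        responded = responded,
                        latency_s = ifelse(responded, lat, NA_real_),
                        amplitude = ifelse(responded, amp, NA_real_)),
        motion = motion, slow = slow, config = config)
    )
  })
}

#' Generate a particle layout at a given surface density
#'
#' Places `round(density * area / particle_mass)` particles on a square
#' lattice or uniformly at random (Poisson) in a square region and returns
#' nearest-neighbour distances. For the lattice the nearest-neighbour
#' distance equals the lattice constant `(n / area)^(-1/2)`; for Poisson
#' placement its expectation is half that value.
#'
#' @param density Surface mass density in ug mm^-2 (> 0).
#' @param geometry A [particle_geometry()].
#' @param area_mm2 Region area in mm^2.
#' @param mode `"lattice"` or `"poisson"`.
#' @param seed Optional seed (Poisson mode).
#' @param max_count Guard on the particle count (placement is explicit).
#' @return A list with `positions` (tibble `x_mm`, `y_mm`), `nn_mm`
#'   (nearest-neighbour distance per particle), `count` and
#'   `lattice_constant_mm`.
#' @export
gen_particle_layout <- function(density, geometry = particle_geometry(),
                                area_mm2 = 1e-6,
                                mode = c("lattice", "poisson"), seed = NULL,
                                max_count = 2e5) {
  mode <- match.arg(mode)
  check_number(density, "density", min = 0, strict_min = TRUE)
  check_number(area_mm2, "area_mm2", min = 0, strict_min = TRUE)
  mass_g <- interparticle_spacing(density, geometry)$particle_mass_g
  count <- round(density * 1e-6 * area_mm2 / mass_g)
  if (count < 1) {
    rlang::abort("Fewer than one particle in the region; increase area or density.",
                 class = c("menmod_invalid_input", "menmod_error"))
  }
  if (count > max_count) {
    rlang::abort(sprintf("Particle count %g exceeds max_count = %g; reduce the area.",
                         count, max_count),
                 class = c("menmod_invalid_input", "menmod_error"))
  }
  side <- sqrt(area_mm2)
  spacing <- sqrt(area_mm2 / count)
  if (mode == "lattice") {
    ncol_grid <- ceiling(sqrt(count))
    i <- seq_len(count) - 1
    pos <- tibble(x_mm = (i %% ncol_grid + 0.5) * spacing,
                  y_mm = (i %/% ncol_grid + 0.5) * spacing)
    nn <- if (count > 1) rep(spacing, count) else numeric(0)
  } else {
    pos <- with_local_seed(seed, tibble(x_mm = runif(count, 0, side),
                                        y_mm = runif(count, 0, side)))
    nn <- nearest_neighbour_dist(pos$x_mm, pos$y_mm, side)
  }
  list(positions = pos, nn_mm = nn, count = count,
       lattice_constant_mm = spacing)
}

# bucketed nearest-neighbour search in a square of side `side`
nearest_neighbour_dist <- function(x, y, side) {
  n <- length(x)
  if (n < 2) return(numeric(0))
  g <- max(1L, floor(sqrt(n / 4)))
  cs <- side / g
  cx <- pmin(pmax(floor(x / cs), 0), g - 1)
  cy <- pmin(pmax(floor(y / cs), 0), g - 1)
  cell <- cx * g + cy
  members <- split(seq_len(n), cell)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    ring <- 1L
    repeat {
      xs <- max(0, cx[i] - ring):min(g - 1, cx[i] + ring)
      ys <- max(0, cy[i] - ring):min(g - 1, cy[i] + ring)
      ids <- unlist(members[as.character(outer(xs * g, ys, "+"))],
                    use.names = FALSE)
      ids <- ids[!is.na(ids) & ids != i]
      if (length(ids)) {
        d2 <- (x[ids] - x[i])^2 + (y[ids] - y[i])^2
        best <- min(best, min(d2))
      }
      # a verified neighbour must be closer than the unexplored region
      if (is.finite(best) && sqrt(best) <= ring * cs) break
      if (length(xs) == g && length(ys) == g) break
      ring <- ring + 1L
    }
    nn[i] <- sqrt(best)
  }
  nn
}
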