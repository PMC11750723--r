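make_rec <- function(sig470, iso405, fs = 130, onsets = 10, stim = 5) {
  n <- length(sig470)
  photometry_recording(time_s = (seq_len(n) - 1) / fs, sig470 = sig470,
                       iso405 = iso405, fs = fs, stim_onsets = onsets,
                       stim_duration = stim)
}

test_that("low-pass filter has unit DC gain and is linear", {
  n <- 130 * 30
  const <- make_rec(rep(7, n), rep(3, n))
  out <- pm_lowpass(const)
  core <- seq(130 * 5, n - 130 * 5) # away from filtfilt edge transients
  expect_equal(out$sig470[core], rep(7, length(core)), tolerance = 1e-8)
  expect_equal(out$iso405[core], rep(3, length(core)), tolerance = 1e-8)

  with_seed(41, {
    x <- rnorm(n); y <- rnorm(n)
    fx <- pm_lowpass(make_rec(x, x))$sig470
    fy <- pm_lowpass(make_rec(y, y))$sig470
    fxy <- pm_lowpass(make_rec(2 * x + 3 * y, x))$sig470
    expect_equal(fxy, 2 * fx + 3 * fy, tolerance = 1e-10)
  })
  expect_error(pm_lowpass(make_rec(rep(1, 200), rep(1, 200), fs = 40,
                                   onsets = 1)),
               class = "menmod_config_error")
})

test_that("a 40 Hz tone is attenuated at least by the squared single-pass response", {
  fs <- 130
  n <- fs * 60
  tt <- (seq_len(n) - 1) / fs
  tone <- sin(2 * pi * 40 * tt)
  out <- pm_lowpass(make_rec(tone, tone))$sig470
  core <- seq(fs * 5, n - fs * 5) # avoid edge transients
  gain <- sqrt(mean(out[core]^2) / mean(tone[core]^2))
  expect_lte(gain, oracle_butter2_mag2(40, 25, fs) * 1.02)
})

test_that("debleaching recovers a pure double exponential to numerical precision", {
  tt <- seq(0, 600, by = 0.2)
  y <- 20 * exp(-tt / 60) + 80 * exp(-tt / 3000)
  fit <- fit_debleach(y, tt)
  expect_equal(fit$model, "exp2")
  expect_lt(max(abs(y - fit$fitted)), 1e-6 * 20)
  resid <- debleach(y, tt)
  expect_lt(max(abs(resid)), 1e-6 * 20)
})

test_that("a constant channel debleaches to a ~zero residual", {
  tt <- seq(0, 100, by = 0.5)
  y <- rep(42, length(tt))
  resid <- suppressWarnings(debleach(y, tt))
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("masking the transient support preserves its amplitude after debleaching", {
  tt <- seq(0, 600, by = 1 / 10)
  bleach <- 15 * exp(-tt / 90) + 85 * exp(-tt / 4000)
  transient <- 5 * exp(-pmax(tt - 300, 0) / 10) * (tt >= 300)
  y <- bleach + transient
  mask <- tt >= 300 & tt < 400
  resid <- debleach(y, tt, mask = mask)
  expect_lt(abs(max(resid[mask]) - 5) / 5, 0.05)
})

test_that("motion subtraction cancels shared artifacts and flips 405-only ones", {
  expect_equal(motion_subtract(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_error(motion_subtract(1:3, 1:4), class = "menmod_invalid_input")
  art <- c(0, 0.5, 1, 0.5, 0)
  expect_equal(motion_subtract(rep(0, 5), art), -art)
})

test_that("a shared motion artifact is suppressed at least tenfold by the pipeline", {
  cfg <- photometry_sim_config(n_trials = 3, inter_trial = 60,
                               first_onset = 120, p_trial = 0,
                               motion_sd = 0.02, slow_sd = 0, noise_sd = 0,
                               secondary_amplitude = 0, tail = 60, seed = 42)
  s <- gen_photometry_session(cfg)
  proc <- pm_process(s$recording)
  uncorrected <- proc$sig470_corr
  corrected <- proc$motion_corrected
  expect_gt(sd(uncorrected) / sd(corrected), 10)
})

test_that("trial segmentation matches a hand-computed two-trial example", {
  # constant 10 before each onset, step to 12 after the first onset only
  fs <- 1
  tt <- 0:99
  x <- rep(10, 100)
  x[tt >= 20 & tt < 30] <- 12
  segs <- segment_trials(x, tt, onsets = c(20, 60), pre = 10, post = 20)
  s1 <- segs[segs$trial == 1, ]
  s2 <- segs[segs$trial == 2, ]
  expect_equal(unique(s1$f0), 10)
  expect_equal(s1$dff[s1$time_rel_s >= 0 & s1$time_rel_s < 10],
               rep(0.2, 10))
  expect_equal(unique(s2$dff), 0)
})

test_that("segmentation drops edge trials with a warning and zero baselines with exclusion", {
  tt <- 0:199
  x <- rep(5, 200)
  expect_warning(
    segs <- segment_trials(x, tt, onsets = c(50, 120, 190), pre = 30,
                           post = 50),
    "edge")
  expect_equal(sort(unique(segs$trial)), c(1, 2))
  xneg <- x; xneg[1:40] <- -1
  expect_warning(segment_trials(xneg, tt, onsets = 31, pre = 30, post = 50),
                 "non-positive baseline")
})

test_that("constant signals give zero dF/F0 in every segment", {
  tt <- 0:299
  segs <- segment_trials(rep(8, 300), tt, onsets = c(60, 150), pre = 30,
                         post = 100)
  expect_true(all(segs$dff == 0))
})

test_that("trial classification measures a triangular transient's width analytically", {
  # baseline: deterministic alternating +/- a, sd known exactly
  fs <- 10
  pre_n <- 300
  a <- 0.01
  base <- rep(c(a, -a), length.out = pre_n)
  sig_exact <- sd(base)
  h <- 0.5
  w <- 4 # half-base in seconds
  post_t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  tri <- pmax(0, h * (1 - abs(post_t - 10) / w))
  seg <- tibble::tibble(
    time_rel_s = c(seq(-pre_n / fs, -1 / fs, by = 1 / fs), post_t),
    dff = c(base, tri))
  m <- classify_trial(seg, sigma_k = 2, response_window = 20)
  expect_true(m$responsive)
  expect_equal(m$peak_position_s, 10)
  expect_equal(m$peak_intensity, h)
  # similar triangles: width at level sig/2 on both flanks
  width_expected <- 2 * w * (1 - (sig_exact / 2) / h)
  expect_lt(abs(m$peak_width_s - width_expected), 1 / fs)
})

test_that("a planted transient peaking at onset + 3 s is located exactly", {
  cfg <- photometry_sim_config(n_trials = 1, first_onset = 330, p_trial = 1,
                               latency_mean = 3, latency_sd = 0,
                               motion_sd = 0, slow_sd = 0, noise_sd = 0,
                               secondary_amplitude = 0, seed = 43)
  s <- gen_photometry_session(cfg)
  m <- analyze_photometry(s$recording)
  expect_true(m$responsive[1])
  expect_lt(abs(m$peak_position_s[1] - 3), 2 / 130)
  expect_lt(abs(m$peak_intensity[1] - s$truth$trials$amplitude[1]) /
              s$truth$trials$amplitude[1], 0.05)
})

test_that("pure-noise trials classify at a rate consistent with a Monte-Carlo oracle", {
  with_seed(44, {
    fs <- 5
    pre_n <- 30 * fs
    post_n <- 25 * fs
    run_rule <- function(x_pre, x_post) {
      sig <- sd(x_pre)
      any(x_post[seq_len(20 * fs)] >= 2 * sig)
    }
    nrep <- 400
    # oracle: direct loop over the rule
    oracle_hits <- vapply(seq_len(nrep), function(i) {
      run_rule(rnorm(pre_n), rnorm(post_n))
    }, logical(1))
    # implementation: classify_trial on equivalent segments
    impl_hits <- vapply(seq_len(nrep), function(i) {
      seg <- tibble::tibble(
        time_rel_s = seq(-pre_n, post_n - 1) / fs,
        dff = rnorm(pre_n + post_n))
      classify_trial(seg, sigma_k = 2, response_window = 20)$responsive
    }, logical(1))
    p1 <- mean(oracle_hits)
    p2 <- mean(impl_hits)
    se <- sqrt(p1 * (1 - p1) / nrep + p2 * (1 - p2) / nrep)
    expect_lt(abs(p1 - p2), 4 * se + 0.01)
  })
})

test_that("session statistics reproduce hand-computed per-animal fractions", {
  m <- tibble::tibble(
    animal = c(rep("m1", 5), rep("m2", 5)),
    responsive = c(rep(TRUE, 4), FALSE, c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  st <- session_statistics(m)
  expect_equal(st$spiking_probability[st$animal == "m1"], 0.8)
  two <- session_statistics(tibble::tibble(
    animal = rep(c("a", "b"), each = 5),
    responsive = c(rep(TRUE, 5), rep(c(TRUE, FALSE), length.out = 5))))
  expect_equal(attr(two, "mean"), (1 + 0.6) / 2)
  expect_equal(attr(two, "sd"), sd(c(1, 0.6)))
  all_resp <- session_statistics(tibble::tibble(responsive = rep(TRUE, 4)))
  expect_equal(all_resp$spiking_probability, 1)
  expect_equal(attr(all_resp, "sd"), 0)
})

test_that("dF/F0 from the pipeline is invariant under common channel gain", {
  cfg <- photometry_sim_config(n_trials = 2, inter_trial = 60,
                               first_onset = 120, p_trial = 1, tail = 100,
                               seed = 45)
  s <- gen_photometry_session(cfg)
  rec2 <- photometry_recording(
    time_s = s$recording$time_s,
    sig470 = 2.5 * s$recording$sig470,
    iso405 = 2.5 * s$recording$iso405,
    fs = 130, stim_onsets = attr(s$recording, "stim_onsets"),
    stim_duration = attr(s$recording, "stim_duration"))
  m1 <- analyze_photometry(s$recording, pre = 30, post = 100)
  m2 <- analyze_photometry(rec2, pre = 30, post = 100)
  expect_equal(m2$peak_intensity, m1$peak_intensity, tolerance = 1e-4)
  expect_equal(m2$responsive, m1$responsive)
})

test_that("filtering is idempotent on already band-limited signals", {
  fs <- 130
  n <- fs * 30
  tt <- (seq_len(n) - 1) / fs
  x <- sin(2 * pi * 2 * tt) + 0.5 * cos(2 * pi * 5 * tt)
  once <- pm_lowpass(make_rec(x, x))
  twice <- pm_lowpass(once)
  core <- seq(fs * 5, n - fs * 5)
  expect_lt(max(abs(twice$sig470[core] - once$sig470[core])), 1e-3)
})
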