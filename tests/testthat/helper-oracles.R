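# independent oracles used across the suite; deliberately written as plain
# loops / closed forms, not via the package's code paths

# closed-form lattice sum: g = 1 + 2 e^-x / (1 - e^-x)
oracle_g <- function(d, lambda) {
  x <- d / lambda
  1 + 2 * exp(-x) / (1 - exp(-x))
}

# plain O(n^2-ish) peak scan: strictly above both neighbouring distinct
# values, plateaus counted once at their first index
oracle_peaks <- function(x, threshold, base = 0) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2
  while (i <= n - 1) {
    j <- i
    while (j < n && x[j + 1] == x[i]) j <- j + 1
    if (x[i - 1] < x[i] && j < n && x[j + 1] < x[i]) peaks <- c(peaks, i)
    i <- j + 1
  }
  sum(x[peaks] - base > threshold)
}

# Monte-Carlo oracle for the 3-sigma/any-frame responsiveness rule on pure
# white noise (relative units), pooled-sigma variant
oracle_fp_rate <- function(n_cells, nb, nw, k, nrep = 200) {
  hits <- 0
  total <- 0
  for (r in seq_len(nrep)) {
    b <- matrix(rnorm(n_cells * nb), n_cells)
    w <- matrix(rnorm(n_cells * nw), n_cells)
    f0 <- rowMeans(b)
    sig_pool <- mean(apply(b - f0, 1, sd))
    hit <- apply(w - f0 > k * sig_pool, 1, any)
    hits <- hits + sum(hit)
    total <- total + n_cells
  }
  hits / total
}

# analytic squared magnitude of a bilinear-transform 2nd-order Butterworth
# low-pass at frequency f (Hz) for cut-off fc and sampling rate fs
oracle_butter2_mag2 <- function(f, fc, fs) {
  ratio <- tan(pi * f / fs) / tan(pi * fc / fs)
  1 / (1 + ratio^4)
}

# truncated-normal (lower bound 0) mean and sd by numeric integration
oracle_truncnorm_moments <- function(mu, sigma) {
  z <- 1 - pnorm(0, mu, sigma)
  m1 <- integrate(function(x) x * dnorm(x, mu, sigma), 0, Inf,
                  rel.tol = 1e-10)$value / z
  m2 <- integrate(function(x) x^2 * dnorm(x, mu, sigma), 0, Inf,
                  rel.tol = 1e-10)$value / z
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

# run an expression with a local seed without disturbing the global stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# build a tiny trace_matrix with a short baseline for worked examples
tiny_traces <- function(values, fps = 1, onsets = 2, epoch_duration = 1) {
  trace_matrix(values, fps = fps, onsets = onsets,
               epoch_duration = epoch_duration)
}

tiny_config <- function(...) {
  calcium_config(baseline_window = 2, response_window = 2, ...)
}
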