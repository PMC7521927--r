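# Shared fixtures, memoised so expensive simulations run once per suite.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 120 s naturalistic stimulus shared by several estimator tests
fix_stimulus <- function() memo("stim120",
  generate_naturalistic_stimulus(stimulus_spec(duration = 120, seed = 7)))

# 60 s stimulus used by the reconstruction oracle tests
fix_stimulus60 <- function() memo("stim60",
  generate_naturalistic_stimulus(stimulus_spec(duration = 60, seed = 21)))

# default 24-neuron cohort (CV 0.1-0.8 x 3 seeds, fixed rate/sensitivity)
fix_cohort <- function() memo("cohort", run_cohort(cohort_config()))

# band-limited white Gaussian trace built independently of the stimulus
# generator (brickwall in the frequency domain)
white_band_trace <- function(n, fmax, sd_target, seed, fs = 1000) {
  with_seed(seed, {
    x <- stats::rnorm(n)
    X <- stats::fft(x)
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    f <- k * fs / n
    X[abs(f) > fmax | f == 0] <- 0
    y <- Re(stats::fft(X, inverse = TRUE)) / n
    trace(y / stats::sd(y) * sd_target, sample_rate = fs)
  })
}

skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
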