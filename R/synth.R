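# Synthetic-cohort generators: naturalistic head-velocity stimuli,
# gamma-renewal resting discharges, LN-cascade stimulus-driven responses,
# repeated trials, and model eye movements with optional quick phases.

#' Specification of a naturalistic head-velocity stimulus
#'
#' The synthetic stimulus emulates naturalistic head yaw velocity: a
#' zero-mean Gaussian process, symmetric about zero, with power confined to
#' the 0-20 Hz band of natural head motion and most of it below a few Hz.
#' It is built as white Gaussian noise passed through a causal first-order
#' low-pass (knee at `corner_freq`), hard band-limited at `max_freq` with a
#' zero-phase cutoff, and rescaled to `target_sd`.
#'
#' @param duration seconds (> 2 s so 0-20 Hz spectral estimates are possible)
#' @param sample_rate Hz, default 1000
#' @param corner_freq low-pass knee (Hz), default 2
#' @param max_freq hard band limit (Hz), default 20
#' @param target_sd stimulus SD (deg/s), default 20
#' @param seed RNG seed
#' @return an object of class `stimulus_spec`
#' @export
stimulus_spec <- function(duration, sample_rate = 1000, corner_freq = 2,
                          max_freq = 20, target_sd = 20, seed = 1) {
  stopifnot(is.numeric(duration), length(duration) == 1L)
  if (duration <= 0) stop("duration must be > 0")
  if (!(corner_freq > 0 && corner_freq < max_freq && max_freq <= sample_rate / 2))
    stop("need 0 < corner_freq < max_freq <= sample_rate/2")
  if (target_sd <= 0) stop("target_sd must be > 0")
  structure(list(duration = duration, sample_rate = sample_rate,
                 corner_freq = corner_freq, max_freq = max_freq,
                 target_sd = target_sd, seed = seed),
            class = "stimulus_spec")
}

#' Generate a naturalistic head-velocity stimulus
#'
#' @param spec a [stimulus_spec()]
#' @return a `trace` (deg/s); zero-mean, Gaussian by construction, SD equal
#'   to `target_sd`, no power above `max_freq`
#' @export
generate_naturalistic_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  if (n < 2 * fs)
    stop("stimulus too short for 0-20 Hz spectral estimates (need >= 2 s)")
  x <- with_seed(derive_seed(spec$seed, "stimulus"), stats::rnorm(n))
  # causal one-pole low-pass, knee at corner_freq
  a <- exp(-2 * pi * spec$corner_freq / fs)
  y <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  # zero-phase hard band limit at max_freq (and remove DC)
  Y <- stats::fft(y)
  f <- dft_freqs(n, fs)
  Y[abs(f) > spec$max_freq | f == 0] <- 0
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  y <- y - mean(y)
  y <- y * spec$target_sd / stats::sd(y)
  trace(y, sample_rate = fs, unit = "deg/s")
}

# signed DFT frequency grid for an n-point transform at rate fs
dft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Specification of a synthetic central vestibular neuron
#'
#' Resting discharge is a gamma-interval renewal process with mean rate
#' `base_rate` and ISI CV `target_cv` (gamma shape k = 1/CV^2). Responses to
#' a stimulus follow an LN cascade: a linear stage with gain `sensitivity`
#' (sp/s per deg/s) and a named kernel template, a static nonlinearity, and
#' spike generation by time-rescaling the same renewal process so that the
#' resting-segment CV is preserved.
#'
#' @param base_rate resting firing rate (sp/s)
#' @param target_cv target ISI CV (0 < cv <= 1.5)
#' @param sensitivity linear-stage gain, (sp/s)/(deg/s), >= 0
#' @param kernel list(shape = "lowpass"|"bandpass"|"none", corner = Hz);
#'   "lowpass" is a causal one-pole with unity DC gain, "bandpass" adds a
#'   one-pole high-pass at `corner/10`
#' @param nonlinearity list(type = "identity") or
#'   list(type = "rectifier", threshold = sp/s, slope = dimensionless)
#' @param seed RNG seed
#' @param class_label "PVP", "EH" or "VO" (metadata only)
#' @return an object of class `neuron_spec`
#' @export
neuron_spec <- function(base_rate = 50, target_cv = 0.5, sensitivity = 0.5,
                        kernel = list(shape = "lowpass", corner = 30),
                        nonlinearity = list(type = "identity"),
                        seed = 1, class_label = c("VO", "PVP", "EH")) {
  class_label <- match.arg(class_label)
  if (base_rate <= 0) stop("base_rate must be > 0")
  if (!(target_cv > 0 && target_cv <= 1.5))
    stop("target_cv must be in (0, 1.5]")
  if (sensitivity < 0) stop("sensitivity must be >= 0")
  stopifnot(kernel$shape %in% c("lowpass", "bandpass", "none"))
  stopifnot(nonlinearity$type %in% c("identity", "rectifier"))
  structure(list(base_rate = base_rate, target_cv = target_cv,
                 sensitivity = sensitivity, kernel = kernel,
                 nonlinearity = nonlinearity, seed = seed,
                 class_label = class_label),
            class = "neuron_spec")
}

#' Generate a gamma-interval renewal spike train
#'
#' Interspike intervals are i.i.d. gamma with shape k = 1/cv^2 and mean
#' 1/rate, so the ISI CV equals `cv` exactly in expectation (cv = 1 is a
#' Poisson process).
#'
#' @param rate mean firing rate (sp/s)
#' @param cv target ISI CV (> 0)
#' @param duration seconds
#' @param seed RNG seed
#' @param sample_rate binarization grid (Hz)
#' @return a `spike_train`
#' @export
generate_renewal_spiketrain <- function(rate, cv, duration, seed,
                                        sample_rate = 1000) {
  if (cv <= 0) stop("cv must be > 0")
  if (rate <= 0 || duration <= 0) stop("rate and duration must be > 0")
  k <- 1 / cv^2
  with_seed(derive_seed(seed, "renewal"), {
    tt <- numeric(0)
    t_end <- 0
    while (t_end < duration) {
      m <- max(100L, ceiling((duration - t_end) * rate * 1.5))
      isis <- stats::rgamma(m, shape = k, rate = k * rate)
      tt <- c(tt, t_end + cumsum(isis))
      t_end <- tt[length(tt)]
    }
    spike_train(tt[tt < duration], duration, sample_rate)
  })
}

# deterministic linear drive of the LN cascade (sp/s, zero-mean for a
# zero-mean stimulus); gain normalized so |H(f)| ~ sensitivity in-band
ln_linear_drive <- function(stimulus, spec) {
  fs <- stimulus$sample_rate
  x <- stimulus$values
  k <- spec$kernel
  if (k$shape == "none") return(spec$sensitivity * x)
  a <- exp(-2 * pi * k$corner / fs)
  y <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  if (k$shape == "bandpass") {
    ah <- exp(-2 * pi * (k$corner / 10) / fs)
    # one-pole high-pass: x - lowpass(x)
    lp <- as.numeric(stats::filter(y * (1 - ah), ah, method = "recursive"))
    y <- y - lp
  }
  spec$sensitivity * y
}

ln_apply_nonlinearity <- function(drive, spec) {
  nl <- spec$nonlinearity
  if (nl$type == "identity") return(drive)
  slope <- if (is.null(nl$slope)) 1 else nl$slope
  thr <- if (is.null(nl$threshold)) 0 else nl$threshold
  pmax(0, slope * (drive - thr))
}

#' Deterministic instantaneous firing rate of the LN cascade
#'
#' rate(t) = max(0, base_rate + nonlinearity(kernel %*% stimulus)); the
#' stochastic response is obtained by time-rescaling a gamma renewal process
#' through the integral of this rate.
#'
#' @param stimulus a `trace` at 1 kHz
#' @param spec a [neuron_spec()]
#' @return a `trace` of rate (sp/s)
#' @export
ln_rate <- function(stimulus, spec) {
  stopifnot(inherits(stimulus, "trace"), inherits(spec, "neuron_spec"))
  r <- pmax(0, spec$base_rate +
              ln_apply_nonlinearity(ln_linear_drive(stimulus, spec), spec))
  trace(r, sample_rate = stimulus$sample_rate, unit = "sp/s")
}

# draw a spike train by time-rescaling a unit-rate gamma renewal process
# through the cumulative intensity of `rate_values` (sp/s at fs)
time_rescaled_gamma_train <- function(rate_values, cv, fs, seed) {
  k <- 1 / cv^2
  lam <- pmax(rate_values, 1e-9) / fs
  Lambda <- c(0, cumsum(lam))              # operational time at bin edges
  total <- Lambda[length(Lambda)]
  with_seed(seed, {
    ops <- numeric(0)
    s <- 0
    while (s < total) {
      m <- max(100L, ceiling((total - s) * 1.5))
      isis <- stats::rgamma(m, shape = k, rate = k)
      ops <- c(ops, s + cumsum(isis))
      s <- ops[length(ops)]
    }
    ops <- ops[ops < total]
    grid_t <- (0:(length(Lambda) - 1L)) / fs
    tt <- stats::approx(Lambda, grid_t, xout = ops, ties = "ordered")$y
    tt <- tt[!is.na(tt)]
    tt <- tt[c(TRUE, diff(tt) > 0)]        # guard exact ties on flat spans
    spike_train(tt, duration = length(rate_values) / fs, sample_rate = fs)
  })
}

#' Generate an LN-cascade response to a stimulus
#'
#' Spikes are drawn by time-rescaling the gamma renewal process of
#' [generate_renewal_spiketrain()] through the cumulative LN rate, so the
#' resting-segment ISI CV stays close to `target_cv` while the rate follows
#' the stimulus. During intervals flagged in `suppress` (e.g. quick phases)
#' the rate is set to zero (the neuron pauses).
#'
#' @param stimulus a `trace` at 1 kHz
#' @param spec a [neuron_spec()]
#' @param suppress optional `segment_mask` of epochs with suppressed firing
#' @param seed RNG seed; defaults to `spec$seed`
#' @return a `spike_train`
#' @export
generate_ln_response <- function(stimulus, spec, suppress = NULL, seed = NULL) {
  stopifnot(inherits(stimulus, "trace"))
  if (stimulus$sample_rate != 1000)
    stop("stimulus must be sampled at 1 kHz")
  r <- ln_rate(stimulus, spec)$values
  if (!is.null(suppress) && nrow(suppress$intervals) > 0) {
    fs <- stimulus$sample_rate
    for (k in seq_len(nrow(suppress$intervals))) {
      i0 <- floor(suppress$intervals[k, 1] * fs) + 1L
      i1 <- min(floor(suppress$intervals[k, 2] * fs), length(r))
      if (i1 >= i0) r[i0:i1] <- 0
    }
  }
  if (is.null(seed)) seed <- spec$seed
  time_rescaled_gamma_train(r, spec$target_cv, stimulus$sample_rate,
                            derive_seed(seed, "ln_response"))
}

#' Generate repeated trials of the LN response to a frozen stimulus
#'
#' All trials share the deterministic LN drive; spiking noise is independent
#' across trials (distinct derived sub-seeds). Supplying explicit per-trial
#' seeds with duplicates is refused, since identical seeds would produce
#' identical trains.
#'
#' @param stimulus a `trace` at 1 kHz
#' @param spec a [neuron_spec()]
#' @param n_trials number of repeats (>= 2)
#' @param seed master seed for the trial set
#' @param seeds optional explicit per-trial seeds (must be distinct)
#' @return list of `spike_train`
#' @export
generate_trials <- function(stimulus, spec, n_trials, seed = spec$seed,
                            seeds = NULL) {
  if (n_trials < 2) stop("n_trials must be >= 2")
  if (is.null(seeds))
    seeds <- vapply(seq_len(n_trials),
                    function(i) derive_seed(seed, paste0("trial", i)), 1L)
  if (length(seeds) != n_trials) stop("need one seed per trial")
  if (anyDuplicated(seeds))
    stop("duplicated trial seeds would produce identical spike trains")
  r <- ln_rate(stimulus, spec)$values
  lapply(seeds, function(s)
    time_rescaled_gamma_train(r, spec$target_cv, stimulus$sample_rate, s))
}

#' Generate a synthetic VOR neuron's response to head velocity
#'
#' The neuron's rate modulation is the sensory half of the VOR cascade
#' (canal afferents and vestibular-nucleus dynamics, [vor_neuron_drive()])
#' added to a resting rate, and spikes are drawn by time-rescaling a gamma
#' renewal process with the requested ISI CV -- the same noise model used
#' for [generate_ln_response()].
#'
#' @param head head-velocity `trace` at 1 kHz
#' @param params a [vor_params()]
#' @param base_rate resting firing rate (sp/s)
#' @param cv target resting ISI CV
#' @param seed RNG seed
#' @return a `spike_train`
#' @export
generate_vor_neuron <- function(head, params = vor_params(), base_rate = 50,
                                cv = 0.3, seed = 1) {
  stopifnot(inherits(head, "trace"))
  drive <- vor_neuron_drive(head, params)
  time_rescaled_gamma_train(pmax(base_rate + drive$values, 0), cv,
                            head$sample_rate,
                            derive_seed(seed, "vor_neuron_spikes"))
}

#' Generate model compensatory eye movements with optional quick phases
#'
#' Slow-phase eye velocity is the VOR transfer-function cascade applied to
#' the head trace ([simulate_vor()]). Quick phases, if requested, are
#' Poisson-timed brief (40-80 ms) half-sine velocity transients whose sign
#' opposes the current slow-phase excursion (resetting movements); a mask
#' marks them so they can be excluded from slow-phase analyses.
#'
#' @param head head-velocity `trace` at 1 kHz (deg/s)
#' @param params a [vor_params()]
#' @param quick_phase_rate mean quick-phase rate (Hz), 0 for none
#' @param seed RNG seed
#' @return list with `eye_velocity` (`trace`) and `quick_phase_mask`
#'   (`segment_mask`)
#' @export
generate_eye_movement <- function(head, params = vor_params(),
                                  quick_phase_rate = 0, seed = 1) {
  stopifnot(inherits(head, "trace"))
  if (head$sample_rate != 1000) stop("head trace must be sampled at 1 kHz")
  ev <- simulate_vor(head, params)
  fs <- head$sample_rate
  dur <- duration_s(head)
  if (quick_phase_rate <= 0)
    return(list(eye_velocity = ev,
                quick_phase_mask = segment_mask(matrix(numeric(0), ncol = 2),
                                                "quick_phase")))
  with_seed(derive_seed(seed, "quick_phases"), {
    n_qp <- stats::rpois(1, quick_phase_rate * dur)
    onsets <- sort(stats::runif(n_qp, 0, dur - 0.08))
    # enforce a minimal gap so transients never overlap
    if (length(onsets) > 1) onsets <- onsets[c(TRUE, diff(onsets) > 0.1)]
    widths <- stats::runif(length(onsets), 0.04, 0.08)
    peaks <- stats::runif(length(onsets), 150, 350)
    v <- ev$values
    iv <- matrix(numeric(0), ncol = 2)
    for (k in seq_along(onsets)) {
      i0 <- floor(onsets[k] * fs) + 1L
      i1 <- min(i0 + round(widths[k] * fs) - 1L, length(v))
      idx <- i0:i1
      sgn <- -sign(v[i0])
      if (sgn == 0) sgn <- 1
      v[idx] <- v[idx] + sgn * peaks[k] * sin(pi * seq_along(idx) / length(idx))
      iv <- rbind(iv, c((i0 - 1L) / fs, i1 / fs))
    }
    list(eye_velocity = trace(v, sample_rate = fs, unit = "deg/s"),
         quick_phase_mask = segment_mask(iv, "quick_phase"))
  })
}
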