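# VOR pathway transfer-function model: canal afferents -> vestibular-nucleus
# VOR neurons -> neural integrator -> extraocular plant; spike-driven
# eye-velocity prediction, matching index, and regression VOR gain.

#' VOR cascade parameters
#'
#' Time constants of the four-stage transfer-function model: `T1`, `T2`, `Tc`
#' shape sensory transduction and canal afferent dynamics (torsion pendulum
#' plus lead term), `T_vor` is the velocity-storage VOR time constant, `Te1`
#' and `Te2` describe the neural integrator and oculomotor plant, `tau` is
#' the conduction/processing delay, and `g_vor` the overall VOR gain.
#'
#' @param T1,T2,Tc,T_vor,Te1,Te2,tau time constants (s), all > 0
#' @param g_vor dimensionless VOR gain, default 1
#' @return list of class `vor_params`
#' @export
vor_params <- function(T1 = 0.0175, T2 = 0.0027, Tc = 5.7, T_vor = 16,
                       Te1 = 1, Te2 = 0.016, tau = 0.008, g_vor = 1) {
  vals <- c(T1 = T1, T2 = T2, Tc = Tc, T_vor = T_vor, Te1 = Te1, Te2 = Te2,
            tau = tau)
  if (any(vals <= 0)) stop("all time constants must be > 0")
  structure(as.list(c(vals, g_vor = g_vor)), class = "vor_params")
}

#' Complex gain of one VOR cascade stage
#'
#' Stage transfer functions (s = 2*pi*i*f):
#' \itemize{
#'   \item afferents: s Tc (1 + s T1) / ((1 + s T2)(1 + s Tc))
#'   \item vn (VOR neurons): -g_vor (T_vor/Tc) (1 + s Tc) / (1 + s T_vor)
#'   \item ni (neural integrator): (s Te1 + 1) / s  (pole at f = 0)
#'   \item plant: s e^(-s tau) / ((s Te1 + 1)(s Te2 + 1))
#' }
#' In the composite pathway the canal time constant Tc cancels between the
#' afferent and VOR-neuron stages (velocity storage replaces it with T_vor),
#' and the integrator pole cancels against the plant zero, so the full
#' head-to-eye response is a delayed first-order low-pass with a high-pass
#' cut below ~1/(2 pi T_vor).
#'
#' @param params a [vor_params()]
#' @param f frequency (Hz); `f = 0` is a pole for the integrator stage
#'   (returned as `Inf`)
#' @param stage one of "afferents", "vn", "ni", "plant"
#' @return complex gain, same length as `f`
#' @export
stage_response <- function(params, f, stage = c("afferents", "vn", "ni",
                                                "plant")) {
  stage <- match.arg(stage)
  p <- params
  s <- 2i * pi * f
  switch(stage,
    afferents = s * p$Tc * (1 + s * p$T1) /
      ((1 + s * p$T2) * (1 + s * p$Tc)),
    vn = -p$g_vor * (p$T_vor / p$Tc) * (1 + s * p$Tc) / (1 + s * p$T_vor),
    ni = ifelse(f == 0, complex(real = Inf),
                (s * p$Te1 + 1) / s),
    plant = s * exp(-s * p$tau) / ((s * p$Te1 + 1) * (s * p$Te2 + 1)))
}

# composite pathway gains in cancellation-safe (simplified) form:
#   sensory = afferents x vn  = -g s T_vor (1+sT1)/((1+sT2)(1+sT_vor))
#   motor   = ni x plant      = e^(-s tau)/(1 + s Te2)
#   full    = sensory x motor
vor_pathway_gain <- function(params, f,
                             which = c("full", "sensory", "motor")) {
  which <- match.arg(which)
  p <- params
  s <- 2i * pi * f
  sensory <- -p$g_vor * s * p$T_vor * (1 + s * p$T1) /
    ((1 + s * p$T2) * (1 + s * p$T_vor))
  motor <- exp(-s * p$tau) / (1 + s * p$Te2)
  switch(which, sensory = sensory, motor = motor,
         full = sensory * motor)
}

# apply a frequency response (function of signed f) to a real signal
apply_freq_response <- function(values, fs, gain_fn) {
  n <- length(values)
  f <- dft_freqs(n, fs)
  G <- gain_fn(f)
  G[f == 0] <- 0  # DC removed: zero-mean pathway output
  Re(stats::fft(stats::fft(values) * G, inverse = TRUE)) / n
}

#' Simulate compensatory eye velocity from head velocity
#'
#' Frequency-domain application of the full cascade
#' EV(f) = T_afferents T_VN T_NI T_plant HV(f) (conjugate-symmetric, DC
#' removed), inverse-transformed to a real eye-velocity trace. With
#' `g_vor = 1` the output closely mirrors `-head` over the naturalistic
#' band.
#'
#' @param head head-velocity `trace` at 1 kHz
#' @param params a [vor_params()]
#' @return eye-velocity `trace` (deg/s)
#' @export
simulate_vor <- function(head, params = vor_params()) {
  stopifnot(inherits(head, "trace"))
  if (head$sample_rate != 1000) stop("head trace must be sampled at 1 kHz")
  ev <- apply_freq_response(head$values, head$sample_rate,
                            function(f) vor_pathway_gain(params, f, "full"))
  trace(ev, sample_rate = head$sample_rate, unit = "deg/s")
}

#' Rate modulation of model VOR neurons driven by head velocity
#'
#' R_VOR(f) = T_afferents T_VN HV(f): the sensory half of the cascade,
#' returned as a zero-mean rate-modulation trace (sp/s) suitable as the
#' drive of a synthetic VOR neuron.
#'
#' @param head head-velocity `trace` at 1 kHz
#' @param params a [vor_params()]
#' @return a `trace` (sp/s, zero-mean)
#' @export
vor_neuron_drive <- function(head, params = vor_params()) {
  stopifnot(inherits(head, "trace"))
  v <- apply_freq_response(head$values, head$sample_rate,
                           function(f) vor_pathway_gain(params, f, "sensory"))
  trace(v, sample_rate = head$sample_rate, unit = "sp/s")
}

#' Predict eye velocity from a VOR neuron's spike train
#'
#' The binarized spike train (mean rate subtracted, so the integrator pole
#' never integrates the DC rate) is passed through the downstream decoders
#' T_NI T_plant; the predicted eye-velocity trace and its power spectrum are
#' returned. A noiseless model-consistent rate modulation reproduces
#' [simulate_vor()]'s output.
#'
#' @param train a `spike_train` at 1 kHz
#' @param params a [vor_params()]
#' @param window_s,n_tapers,segments spectral settings for the returned
#'   spectrum
#' @return list with `eye_velocity` (`trace`) and `spectrum`
#'   (`spectral_estimate`, trace convention)
#' @export
predict_eye_from_spikes <- function(train, params = vor_params(),
                                    window_s = 2.048, n_tapers = 4,
                                    segments = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) == 0) stop("empty spike train")
  if (train$sample_rate != 1000) stop("spike train must use a 1 kHz grid")
  z <- rate_signal(train)$z
  ev <- apply_freq_response(z, train$sample_rate,
                            function(f) vor_pathway_gain(params, f, "motor"))
  evt <- trace(ev, sample_rate = train$sample_rate, unit = "deg/s")
  list(eye_velocity = evt,
       spectrum = power_spectrum(evt, window_s = window_s,
                                 n_tapers = n_tapers, segments = segments))
}

#' Matching index between predicted and actual eye-velocity spectra
#'
#' mi = max(0, 1 - RMS_f(log P_pred - log P_actual) / SD_f(log P_actual))
#' over the scored band (natural logarithms). mi = 1 iff the spectra are
#' identical on the band, decreases toward 0 as the log-spectral error grows
#' to the scale of the actual spectrum's own log variation, and is invariant
#' to a common rescaling of both spectra. Zero-power bins are floored at
#' 1e-12 of the in-band maximum before taking logs.
#'
#' @param predicted,actual `spectral_estimate`s on a shared grid
#' @param band `c(lo, hi)` Hz, default `c(0, 20)`
#' @return list with `mi`, `band`, `n_bins`
#' @export
matching_index <- function(predicted, actual, band = c(0, 20)) {
  stopifnot(inherits(predicted, "spectral_estimate"),
            inherits(actual, "spectral_estimate"))
  if (length(predicted$freq) != length(actual$freq) ||
      any(abs(predicted$freq - actual$freq) > 1e-9))
    stop("spectra must share the same frequency grid")
  sel <- predicted$freq >= band[1] & predicted$freq <= band[2]
  if (sum(sel) < 3) stop("fewer than 3 bins in the scored band")
  floor_p <- 1e-12 * max(c(predicted$power[sel], actual$power[sel]))
  lp <- log(pmax(predicted$power[sel], floor_p))
  la <- log(pmax(actual$power[sel], floor_p))
  sda <- stats::sd(la)
  mi <- if (sda == 0) {
    if (all(lp == la)) 1 else 0
  } else {
    max(0, 1 - sqrt(mean((lp - la)^2)) / sda)
  }
  list(mi = mi, band = band, n_bins = sum(sel))
}

#' VOR gain from head and eye velocity by linear regression
#'
#' Gain is the opposite of the slope of the ordinary least-squares regression
#' of eye velocity on head velocity over retained samples; epochs in
#' `exclude` (saccades, quick phases) are dropped before fitting.
#'
#' @param head,eye aligned `trace`s
#' @param exclude optional `segment_mask` of epochs to drop
#' @return list with `gain`, `slope`, `r_squared`, `n_samples`
#' @export
vor_gain <- function(head, eye, exclude = NULL) {
  stopifnot(inherits(head, "trace"), inherits(eye, "trace"))
  h <- head$values
  e <- eye$values
  stopifnot(length(h) == length(e))
  keep <- rep(TRUE, length(h))
  fs <- head$sample_rate
  if (!is.null(exclude) && nrow(exclude$intervals) > 0) {
    for (k in seq_len(nrow(exclude$intervals))) {
      i0 <- floor(exclude$intervals[k, 1] * fs) + 1L
      i1 <- min(floor(exclude$intervals[k, 2] * fs), length(h))
      if (i1 >= i0) keep[i0:i1] <- FALSE
    }
  }
  if (sum(keep) < fs) stop("fewer than 1 s of retained samples")
  fit <- stats::lm.fit(cbind(1, h[keep]), e[keep])
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((e[keep] - mean(e[keep]))^2)
  list(gain = -unname(slope), slope = unname(slope), r_squared = r2,
       n_samples = sum(keep))
}
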