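# Temporal-whitening index, stimulus-response coherence, mutual-information
# rate (Gaussian-channel coherence lower bound), and coding optimality
# (water-filling capacity given the measured noise spectrum).

#' Temporal whitening index of a spectrum
#'
#' WI = (integral of the power spectrum over the band) divided by
#' (band width x maximum in-band power), i.e. the band integral of the
#' spectrum relative to a simulated white response at the maximum neuron
#' power. WI = 1 for a frequency-independent (whitened) spectrum and
#' decreases as power concentrates at few frequencies. The in-band maximum
#' is taken after 3-point median smoothing so single-bin estimator spikes do
#' not set the white reference level; the integral uses the raw estimate.
#' WI is invariant to overall spectral scaling.
#'
#' @param est a `spectral_estimate` covering the band
#' @param band `c(lo, hi)` Hz, default `c(0, 20)`
#' @return list with `wi`, `band`, `reference_max`
#' @export
whitening_index <- function(est, band = c(0, 20)) {
  stopifnot(inherits(est, "spectral_estimate"))
  sel <- est$freq >= band[1] & est$freq <= band[2]
  if (sum(sel) < 3) stop("spectrum does not cover the band")
  p <- est$power[sel]
  f <- est$freq[sel]
  if (all(p == 0)) stop("all-zero spectrum in band")
  pmax_ref <- max(stats::runmed(p, 3))
  wi <- trapz(f, p) / (diff(range(f)) * pmax_ref)
  list(wi = wi, band = band, reference_max = pmax_ref)
}

#' Whitening index of a head-velocity stimulus
#'
#' Applies [whitening_index()] to the stimulus power spectrum computed with
#' the same estimator used for neural responses.
#'
#' @param stimulus a `trace`
#' @param band `c(lo, hi)` Hz
#' @param window_s,n_tapers,segments estimator settings
#' @return as [whitening_index()]
#' @export
stimulus_whitening_index <- function(stimulus, band = c(0, 20),
                                     window_s = 2.048, n_tapers = 4,
                                     segments = NULL) {
  est <- power_spectrum(stimulus, window_s = window_s, n_tapers = n_tapers,
                        segments = segments)
  whitening_index(est, band = band)
}

#' Stimulus-response coherence
#'
#' C(f) = |P_RS|^2 / (P_RR P_SS), clipped to [0, 1]. Bins where either
#' auto-spectrum vanishes are flagged as undefined (NA).
#'
#' @param response,stimulus `spike_train` or `trace` on the same grid
#' @param window_s,n_tapers,segments estimator settings
#' @return data.frame with `freq`, `coherence`, `defined`
#' @export
coherence <- function(response, stimulus, window_s = 2.048, n_tapers = 4,
                      segments = NULL) {
  a <- rate_signal(response)
  b <- rate_signal(stimulus)
  if (a$fs != b$fs || length(a$z) != length(b$z))
    stop("signals must share the same sampling grid and length")
  est <- mt_csd(a$z, b$z, fs = a$fs, window_s = window_s,
                n_tapers = n_tapers, segments = segments)
  defined <- est$sxx > 0 & est$syy > 0
  C <- rep(NA_real_, length(est$freq))
  C[defined] <- clamp(Mod(est$sxy[defined])^2 /
                        (est$sxx[defined] * est$syy[defined]), 0, 1)
  data.frame(freq = est$freq, coherence = C, defined = defined)
}

#' Mutual-information rate from coherence (Gaussian-channel lower bound)
#'
#' MI = -integral over the band of log2(1 - C(f)) df, in bits/s. Bins with
#' coherence numerically at 1 are capped just below 1 and flagged.
#'
#' @param coh data.frame from [coherence()] (or any with `freq`, `coherence`)
#' @param band `c(lo, hi)` Hz
#' @param cap cap applied to coherence before the log, default `1 - 1e-9`
#' @return list with `mi_rate` (bits/s), `capped` (any bins capped?)
#' @export
mutual_information_rate <- function(coh, band = c(0, 20), cap = 1 - 1e-9) {
  sel <- coh$freq >= band[1] & coh$freq <= band[2] & !is.na(coh$coherence)
  if (sum(sel) < 2) stop("coherence not defined on the band")
  C <- coh$coherence[sel]
  capped <- any(C >= cap)
  C <- pmin(C, cap)
  list(mi_rate = trapz(coh$freq[sel], -log2(1 - C)), capped = capped)
}

# water-filling capacity (bits/s) over a frequency grid given a noise
# spectrum and a total signal-power budget
waterfill_capacity <- function(freq, noise, budget) {
  df <- mean(diff(freq))
  lo <- min(noise)
  hi <- max(noise) + budget / (df * length(freq)) * 2 + lo
  spent <- function(nu) sum(pmax(nu - noise, 0)) * df
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (spent(mid) < budget) lo <- mid else hi <- mid
  }
  nu <- (lo + hi) / 2
  active <- nu > noise
  sum(log2(nu / noise[active])) * df
}

#' Coding optimality: information rate relative to channel capacity
#'
#' The maximum possible information rate for a given level of variability is
#' taken as the Gaussian channel capacity over the band, with the measured
#' noise spectrum as channel noise and a total signal-power budget equal to
#' the measured stimulus-driven response power; allocation across frequencies
#' is by water-filling (or uniform, for sensitivity analysis). Optimality is
#' the measured information rate divided by this capacity, clipped to [0, 1].
#'
#' @param mi_rate measured information rate (bits/s)
#' @param noise a `spectral_estimate` of the noise (e.g. resting or residual
#'   spectrum), positive on the band
#' @param budget total stimulus-driven response power over the band
#'   (integral of the signal spectrum, same units as noise x Hz)
#' @param band `c(lo, hi)` Hz
#' @param allocation "waterfill" (capacity) or "flat" (uniform allocation)
#' @return list with `optimality`, `mi_max` (bits/s), `allocation`
#' @export
optimality <- function(mi_rate, noise, budget, band = c(0, 20),
                       allocation = c("waterfill", "flat")) {
  allocation <- match.arg(allocation)
  stopifnot(inherits(noise, "spectral_estimate"))
  sel <- noise$freq >= band[1] & noise$freq <= band[2]
  if (sum(sel) < 2) stop("noise spectrum does not cover the band")
  N <- noise$power[sel]
  f <- noise$freq[sel]
  if (any(N <= 0)) stop("noise spectrum must be positive on the band")
  if (budget <= 0) {
    warning("zero signal-power budget: optimality undefined")
    return(list(optimality = NA_real_, mi_max = 0, allocation = allocation))
  }
  mi_max <- if (allocation == "waterfill") {
    waterfill_capacity(f, N, budget)
  } else {
    df <- mean(diff(f))
    P <- budget / (df * length(f))
    sum(log2(1 + P / N)) * df
  }
  list(optimality = clamp(mi_rate / mi_max, 0, 1), mi_max = mi_max,
       allocation = allocation)
}
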