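# Multitaper spectral estimation for spike trains and traces.
#
# Core estimator: Welch-style segment averaging (50% overlap) combined with
# orthonormal sine tapers within each window; the per-window mean is removed
# before tapering so the DC line never contaminates the 0-20 Hz band.
#
# Normalization conventions, recorded in every estimate:
#   * "trace": one-sided PSD (unit^2/Hz); its integral over frequency
#     recovers the signal variance (Parseval).
#   * "point_process": two-sided spectral density of the rate signal
#     (binary sequence x fs), reported on a one-sided grid in sp^2/s; a
#     Poisson train of rate lambda is flat at lambda, and a gamma renewal
#     train approaches lambda * CV^2 at low frequencies.

# orthonormal sine tapers, columns k = 1..K over n samples
sine_tapers <- function(n, k) {
  t <- seq_len(n)
  h <- vapply(seq_len(k),
              function(j) sqrt(2 / (n + 1)) * sin(pi * j * t / (n + 1)),
              numeric(n))
  h
}

# enumerate window start indices within concatenated segments so that no
# window straddles a seam; `segments` is a data.frame(start_s, end_s) in the
# current time base (NULL = one segment covering everything)
window_starts <- function(n, fs, segments, nw, step) {
  if (is.null(segments))
    segments <- data.frame(start_s = 0, end_s = n / fs)
  starts <- integer(0)
  for (k in seq_len(nrow(segments))) {
    i0 <- floor(segments$start_s[k] * fs + 1e-9) + 1L
    i1 <- min(floor(segments$end_s[k] * fs + 1e-9), n)
    len <- i1 - i0 + 1L
    if (len < nw) next
    starts <- c(starts, seq(i0, i1 - nw + 1L, by = step))
  }
  starts
}

# Averaged auto-/cross-spectra of one or two real signals.
# Returns two-sided spectral densities evaluated on the one-sided grid:
#   sxx = E|X|^2 / fs, sxy = E[Conj(X) Y] / fs  (tapers have unit energy).
# With this cross convention, y delayed by tau gives phase -2*pi*f*tau, and
# the transfer function x -> y is sxy/sxx.
mt_csd <- function(x, y = NULL, fs, window_s = 2.048, n_tapers = 4,
                   overlap = 0.5, segments = NULL) {
  n <- length(x)
  nw <- round(window_s * fs)
  if (nw < 8) stop("window too short")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- window_starts(n, fs, segments, nw, step)
  if (length(starts) == 0)
    stop("no segment is at least one window long")
  h <- sine_tapers(nw, n_tapers)
  nf <- nw %/% 2 + 1L
  sxx <- numeric(nf)
  syy <- if (!is.null(y)) numeric(nf) else NULL
  sxy <- if (!is.null(y)) complex(nf) else NULL
  for (s0 in starts) {
    xi <- x[s0:(s0 + nw - 1L)]
    xi <- xi - mean(xi)
    if (!is.null(y)) {
      yi <- y[s0:(s0 + nw - 1L)]
      yi <- yi - mean(yi)
    }
    for (k in seq_len(n_tapers)) {
      X <- stats::fft(xi * h[, k])[seq_len(nf)]
      sxx <- sxx + Re(X * Conj(X))
      if (!is.null(y)) {
        Y <- stats::fft(yi * h[, k])[seq_len(nf)]
        syy <- syy + Re(Y * Conj(Y))
        sxy <- sxy + Conj(X) * Y
      }
    }
  }
  m <- length(starts) * n_tapers
  list(freq = (0:(nf - 1L)) * fs / nw,
       sxx = sxx / m / fs,
       syy = if (!is.null(y)) syy / m / fs,
       sxy = if (!is.null(y)) sxy / m / fs,
       n_windows = m,
       resolution = fs / nw)
}

#' Multitaper power spectrum of a spike train or trace
#'
#' Spike trains are binarized at their grid rate, converted to a zero-mean
#' rate signal, and reported as a point-process spectral density (sp^2/s;
#' flat at lambda for Poisson). Traces are reported as a one-sided PSD whose
#' band integral recovers the variance.
#'
#' @param x a `spike_train`, a `trace`, or a numeric rate sequence (sp/s)
#' @param window_s window length (s), default 2.048 (0.49 Hz resolution)
#' @param n_tapers sine tapers per window, default 4
#' @param segments optional boundary list (data.frame `start_s`, `end_s`)
#'   from [mask_and_concatenate()]; windows never straddle a seam
#' @param ... passed to methods
#' @return a `spectral_estimate`
#' @export
power_spectrum <- function(x, ...) UseMethod("power_spectrum")

#' @rdname power_spectrum
#' @export
power_spectrum.spike_train <- function(x, window_s = 2.048, n_tapers = 4,
                                       segments = NULL, ...) {
  fs <- x$sample_rate
  z <- (binarize(x) - length(x$times) / (x$duration * fs)) * fs
  est <- mt_csd(z, fs = fs, window_s = window_s, n_tapers = n_tapers,
                segments = segments)
  spectral_estimate(est$freq, est$sxx, n_windows = est$n_windows,
                    resolution = est$resolution, convention = "point_process")
}

#' @rdname power_spectrum
#' @export
power_spectrum.trace <- function(x, window_s = 2.048, n_tapers = 4,
                                 segments = NULL, ...) {
  est <- mt_csd(x$values, fs = x$sample_rate, window_s = window_s,
                n_tapers = n_tapers, segments = segments)
  # one-sided PSD: double everything except DC (and Nyquist, asymptotically
  # negligible at these window lengths)
  p <- 2 * est$sxx
  p[1] <- est$sxx[1]
  spectral_estimate(est$freq, p, n_windows = est$n_windows,
                    resolution = est$resolution, convention = "trace")
}

#' @rdname power_spectrum
#' @param sample_rate sampling rate for numeric input (Hz)
#' @export
power_spectrum.numeric <- function(x, sample_rate = 1000, window_s = 2.048,
                                   n_tapers = 4, segments = NULL, ...) {
  # rate-trace input (sp/s): point-process density convention so it is
  # directly comparable/additive with spike-train spectra
  est <- mt_csd(x, fs = sample_rate, window_s = window_s,
                n_tapers = n_tapers, segments = segments)
  spectral_estimate(est$freq, est$sxx, n_windows = est$n_windows,
                    resolution = est$resolution, convention = "point_process")
}

# demeaned rate signal (sp/s) of any supported input
rate_signal <- function(x) {
  if (inherits(x, "spike_train")) {
    fs <- x$sample_rate
    list(z = (binarize(x) - length(x$times) / (x$duration * fs)) * fs, fs = fs)
  } else if (inherits(x, "trace")) {
    list(z = x$values - mean(x$values), fs = x$sample_rate)
  } else stop("unsupported type")
}

#' Multitaper cross-spectrum between two signals
#'
#' Spike trains enter as zero-mean rate signals, traces as zero-mean values.
#' The convention is `E[Conj(X) Y]/fs`, so the value for `(x, y)` is the
#' complex conjugate of the value for `(y, x)`, and delaying `y` by `tau`
#' produces a phase slope of `-2*pi*tau` per Hz.
#'
#' @param x,y `spike_train` or `trace` objects on the same grid
#' @inheritParams power_spectrum.spike_train
#' @return list with `freq`, `cross` (complex), `n_windows`, `resolution`
#' @export
cross_spectrum <- function(x, y, window_s = 2.048, n_tapers = 4,
                           segments = NULL) {
  a <- rate_signal(x)
  b <- rate_signal(y)
  if (a$fs != b$fs || length(a$z) != length(b$z))
    stop("signals must share the same sampling grid and length")
  est <- mt_csd(a$z, b$z, fs = a$fs, window_s = window_s,
                n_tapers = n_tapers, segments = segments)
  list(freq = est$freq, cross = est$sxy, n_windows = est$n_windows,
       resolution = est$resolution)
}

#' Poisson surrogate confidence band for a spike-train spectrum
#'
#' Simulates `n` Poisson processes with the same number of spikes and the
#' same duration as the input train, computes each surrogate's spectrum with
#' identical estimator settings, and returns per-frequency percentile bounds.
#' A spectrum inside the band is statistically indistinguishable from a
#' frequency-independent (Poisson) response.
#'
#' @param train a `spike_train`
#' @param window_s,n_tapers,segments estimator settings (as for
#'   [power_spectrum()])
#' @param n number of surrogates, default 1000
#' @param level band level in percent, default 95
#' @param seed RNG seed
#' @return list with `freq`, `low`, `high`, `level`, `n_surrogates`
#' @export
poisson_confidence_band <- function(train, window_s = 2.048, n_tapers = 4,
                                    segments = NULL, n = 1000, level = 95,
                                    seed = 1) {
  stopifnot(inherits(train, "spike_train"))
  n_spk <- length(train$times)
  mats <- with_seed(derive_seed(seed, "poisson_band"), {
    vapply(seq_len(n), function(i) {
      tt <- sort(stats::runif(n_spk, 0, train$duration))
      tt <- tt[c(TRUE, diff(tt) > 0)]
      s <- spike_train(tt, train$duration, train$sample_rate)
      power_spectrum(s, window_s = window_s, n_tapers = n_tapers,
                     segments = segments)$power
    }, numeric(round(window_s * train$sample_rate) %/% 2 + 1L))
  })
  alpha <- (100 - level) / 200
  freq <- (0:(nrow(mats) - 1L)) * train$sample_rate /
    round(window_s * train$sample_rate)
  if (n == 1) {
    low <- high <- mats[, 1]
  } else {
    qs <- apply(mats, 1, stats::quantile, probs = c(alpha, 1 - alpha))
    low <- qs[1, ]; high <- qs[2, ]
  }
  list(freq = freq, low = low, high = high, level = level, n_surrogates = n)
}

#' Trial-to-trial variability (residual) spectrum
#'
#' Residuals are each trial's binarized response minus the across-trial mean;
#' the variability spectrum is the average residual spectrum, scaled by
#' n/(n-1) so it estimates the single-trial noise spectrum (identical trials
#' give exactly zero).
#'
#' @param trials list of `spike_train` (equal duration/grid) or a matrix of
#'   binary sequences (columns = trials)
#' @inheritParams power_spectrum.spike_train
#' @param sample_rate grid rate when `trials` is a matrix
#' @return a `spectral_estimate` (point-process convention)
#' @export
residual_noise_spectrum <- function(trials, window_s = 2.048, n_tapers = 4,
                                    segments = NULL, sample_rate = 1000) {
  B <- trials_matrix(trials, sample_rate)
  n <- ncol(B$mat)
  if (n < 2) stop("need >= 2 trials")
  mu <- rowMeans(B$mat)
  acc <- NULL
  for (j in seq_len(n)) {
    z <- (B$mat[, j] - mu) * B$fs
    est <- mt_csd(z, fs = B$fs, window_s = window_s, n_tapers = n_tapers,
                  segments = segments)
    acc <- if (is.null(acc)) est$sxx else acc + est$sxx
  }
  spectral_estimate(est$freq, acc / n * n / (n - 1),
                    n_windows = est$n_windows, resolution = est$resolution,
                    convention = "point_process")
}

trials_matrix <- function(trials, sample_rate) {
  if (is.matrix(trials)) return(list(mat = trials, fs = sample_rate))
  stopifnot(is.list(trials), length(trials) >= 1)
  fs <- trials[[1]]$sample_rate
  mat <- vapply(trials, function(tr) as.numeric(binarize(tr)),
                numeric(round(trials[[1]]$duration * fs)))
  list(mat = mat, fs = fs)
}

#' Signal / noise / SNR decomposition across repeated trials
#'
#' The noise spectrum is the residual (trial-to-trial variability) spectrum;
#' the signal spectrum is the spectrum of the trial-averaged response with
#' the residual noise bias `noise/n` subtracted (floored at zero); the SNR is
#' their per-frequency ratio where noise power is positive.
#'
#' @inheritParams residual_noise_spectrum
#' @param snr_cap cap applied where noise power vanishes (flagged)
#' @return list with `signal`, `noise` (`spectral_estimate`s), `snr`
#'   (data.frame `freq`, `snr`, `capped`)
#' @export
signal_noise_decomposition <- function(trials, window_s = 2.048, n_tapers = 4,
                                       segments = NULL, sample_rate = 1000,
                                       snr_cap = 1e6) {
  B <- trials_matrix(trials, sample_rate)
  n <- ncol(B$mat)
  if (n < 2) stop("need >= 2 trials")
  noise <- residual_noise_spectrum(trials, window_s = window_s,
                                   n_tapers = n_tapers, segments = segments,
                                   sample_rate = sample_rate)
  mu <- rowMeans(B$mat) * B$fs
  est <- mt_csd(mu - mean(mu), fs = B$fs, window_s = window_s,
                n_tapers = n_tapers, segments = segments)
  sig <- pmax(est$sxx - noise$power / n, 0)
  signal <- spectral_estimate(est$freq, sig, n_windows = est$n_windows,
                              resolution = est$resolution,
                              convention = "point_process")
  capped <- noise$power <= 0
  snr <- ifelse(capped, snr_cap, pmin(sig / pmax(noise$power, 1e-300), snr_cap))
  list(signal = signal, noise = noise,
       snr = data.frame(freq = est$freq, snr = snr, capped = capped))
}
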