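# Linear-nonlinear cascade estimation: transfer function / tuning, static
# nonlinearity, response-spectrum prediction, and the whitening-vs-CV curve.

#' Estimate the linear transfer function from stimulus to response
#'
#' H(f) = P_RS(f) / P_SS(f), where P_RS is the cross-spectrum between the
#' stimulus and the (zero-mean, rate-scaled) binary spike train and P_SS the
#' stimulus power spectrum. The tuning function is G(f) = |H(f)|, and the
#' sensitivity is G at 1 Hz (local interpolation on the estimator grid).
#'
#' @param stimulus a `trace` (deg/s)
#' @param response a `spike_train` (or `trace` of rate) on the same grid
#' @param window_s,n_tapers,segments estimator settings
#' @param band frequency band over which the estimate is considered valid
#' @return list with `freq`, `H` (complex, (sp/s)/(deg/s)), `G`,
#'   `sensitivity_1hz`, estimator metadata
#' @export
estimate_transfer <- function(stimulus, response, window_s = 2.048,
                              n_tapers = 4, segments = NULL,
                              band = c(0, 20)) {
  s <- rate_signal(stimulus)
  r <- rate_signal(response)
  if (s$fs != r$fs || length(s$z) != length(r$z))
    stop("stimulus and response must share the same sampling grid")
  est <- mt_csd(s$z, r$z, fs = s$fs, window_s = window_s,
                n_tapers = n_tapers, segments = segments)
  inband <- est$freq > 0 & est$freq <= band[2]
  if (sum(est$sxx[inband]) <= 0)
    stop("stimulus has no in-band power")
  H <- est$sxy / pmax(est$sxx, .Machine$double.xmin)
  G <- Mod(H)
  structure(list(freq = est$freq, H = H, G = G,
                 sensitivity_1hz = stats::approx(est$freq, G, xout = 1)$y,
                 n_windows = est$n_windows, resolution = est$resolution,
                 window_s = window_s, n_tapers = n_tapers, band = band),
            class = "transfer_estimate")
}

#' Apply an estimated transfer function to a stimulus
#'
#' Interpolates H onto the stimulus DFT grid (conjugate-symmetric, zero DC)
#' and returns the linear prediction (H * S)(t) as a zero-mean rate trace.
#'
#' @param tf a `transfer_estimate`
#' @param stimulus a `trace`
#' @return a `trace` (sp/s, zero-mean)
#' @export
apply_transfer <- function(tf, stimulus) {
  stopifnot(inherits(tf, "transfer_estimate"), inherits(stimulus, "trace"))
  x <- stimulus$values - mean(stimulus$values)
  n <- length(x)
  fs <- stimulus$sample_rate
  f <- dft_freqs(n, fs)
  hre <- stats::approx(tf$freq, Re(tf$H), xout = abs(f), rule = 2)$y
  him <- stats::approx(tf$freq, Im(tf$H), xout = abs(f), rule = 2)$y
  H <- complex(real = hre, imaginary = sign(f) * him)
  H[f == 0] <- 0
  y <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
  trace(y, sample_rate = fs, unit = "sp/s")
}

#' Fit the static nonlinearity of the LN cascade
#'
#' Bins the linear prediction, takes the mean observed firing rate per bin
#' (the actual firing rate plotted as a function of the linear prediction),
#' and interpolates monotonically between bin centers; extrapolation clamps
#' to the end bins. Empty bins are dropped. An all-constant drive yields a
#' flat map at the mean rate.
#'
#' @param linear_drive a `trace` (sp/s) or numeric vector
#' @param firing_rate a `trace` (sp/s) or numeric vector, aligned
#' @param n_bins number of drive bins (>= 5)
#' @return object of class `ln_nonlinearity` with the bin table; evaluate
#'   with [predict_nonlinearity()]
#' @export
fit_nonlinearity <- function(linear_drive, firing_rate, n_bins = 20) {
  if (inherits(linear_drive, "trace")) linear_drive <- linear_drive$values
  if (inherits(firing_rate, "trace")) firing_rate <- firing_rate$values
  stopifnot(length(linear_drive) == length(firing_rate), n_bins >= 5)
  rng <- range(linear_drive)
  if (diff(rng) == 0) {
    tab <- data.frame(drive = rng[1], rate = mean(firing_rate))
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- findInterval(linear_drive, edges, rightmost.closed = TRUE)
    tab <- data.frame(
      drive = tapply(linear_drive, bin, mean),
      rate = tapply(firing_rate, bin, mean))
    tab <- tab[stats::complete.cases(tab), , drop = FALSE]
    tab <- tab[order(tab$drive), , drop = FALSE]
  }
  structure(list(table = tab, n_bins = n_bins), class = "ln_nonlinearity")
}

#' Evaluate a fitted static nonlinearity
#' @param nl an `ln_nonlinearity`
#' @param drive numeric drive values (sp/s)
#' @return predicted firing rate (sp/s, >= 0)
#' @export
predict_nonlinearity <- function(nl, drive) {
  tab <- nl$table
  if (nrow(tab) == 1) return(rep(pmax(tab$rate, 0), length(drive)))
  pmax(stats::approx(tab$drive, tab$rate, xout = drive, rule = 2)$y, 0)
}

# Gaussian smoothing kernel for rate traces used only when fitting the
# nonlinearity (spectra always use unsmoothed sequences); sd 25 ms,
# support ~100 ms
smooth_rate <- function(values, fs, sd_s = 0.025) {
  half <- round(2 * sd_s * fs)
  k <- stats::dnorm(seq(-half, half), sd = sd_s * fs)
  k <- k / sum(k)
  nn <- length(values)
  padded <- c(rep(values[1], half), values, rep(values[nn], half))
  as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + nn)]
}

#' Fit a full LN model (linear stage, nonlinearity, resting spectrum)
#'
#' Convenience wrapper: estimates H from stimulus/response, computes the
#' linear prediction, smooths both the prediction and the binarized firing
#' rate with the same ~100 ms Gaussian kernel, fits the static nonlinearity
#' on the smoothed pair, and attaches the resting-discharge spectrum P0.
#'
#' @param stimulus a `trace`
#' @param response a `spike_train`
#' @param resting a `spike_train` recorded without stimulation
#' @param window_s,n_tapers,segments estimator settings
#' @param n_bins nonlinearity bins
#' @return object of class `ln_model` with `linear`, `nonlinearity`, `p0`
#' @export
fit_ln_model <- function(stimulus, response, resting, window_s = 2.048,
                         n_tapers = 4, segments = NULL, n_bins = 20) {
  tf <- estimate_transfer(stimulus, response, window_s = window_s,
                          n_tapers = n_tapers, segments = segments)
  drive <- apply_transfer(tf, stimulus)
  fs <- stimulus$sample_rate
  rr <- binarize(response) * fs
  base <- length(response$times) / response$duration
  nl <- fit_nonlinearity(smooth_rate(drive$values, fs) + base,
                         smooth_rate(rr, fs), n_bins = n_bins)
  p0 <- power_spectrum(resting, window_s = window_s, n_tapers = n_tapers)
  structure(list(linear = tf, nonlinearity = nl, p0 = p0,
                 base_rate = base,
                 settings = list(window_s = window_s, n_tapers = n_tapers)),
            class = "ln_model")
}

#' Predict the response power spectrum of an LN model
#'
#' P_RR,predicted(f) = P0(f) + P_FR,predicted(f): the resting-discharge
#' spectrum plus the spectrum of the predicted firing rate
#' FR(t) = G((H * S)(t)), computed on the unsmoothed linear prediction. The
#' additivity rests on stimulation noise having the same spectrum as the
#' resting discharge.
#'
#' @param model an `ln_model`
#' @param stimulus a `trace` at the response grid rate
#' @return a `spectral_estimate` (point-process convention) on the model's
#'   estimator grid
#' @export
predict_response_spectrum <- function(model, stimulus) {
  stopifnot(inherits(model, "ln_model"))
  drive <- apply_transfer(model$linear, stimulus)
  fr <- predict_nonlinearity(model$nonlinearity,
                             drive$values + model$base_rate)
  pfr <- power_spectrum(fr, sample_rate = stimulus$sample_rate,
                        window_s = model$settings$window_s,
                        n_tapers = model$settings$n_tapers)
  if (length(pfr$freq) != length(model$p0$freq))
    stop("stimulus grid incompatible with the model's estimator settings")
  spectral_estimate(pfr$freq, pfr$power + model$p0$power,
                    n_windows = pfr$n_windows, resolution = pfr$resolution,
                    convention = "point_process")
}

#' Predicted whitening index across a grid of resting-discharge CVs
#'
#' Holds the linear stage, nonlinearity and firing rate fixed and regenerates
#' the resting spectrum P0 from a matched gamma-renewal train at each CV;
#' the predicted response spectrum P0 + P_FR then yields one whitening index
#' per CV. This isolates the effect of variability on temporal whitening.
#'
#' @param model an `ln_model`
#' @param stimulus a `trace`
#' @param cv_grid CV values (default 0.1 to 1.0)
#' @param rate resting rate for the regenerated trains (sp/s); defaults to
#'   the model's base rate
#' @param rest_duration duration of each regenerated resting train (s)
#' @param seed RNG seed
#' @param band whitening band
#' @return data.frame with `cv`, `wi_predicted`
#' @export
whitening_vs_cv_curve <- function(model, stimulus,
                                  cv_grid = seq(0.1, 1.0, by = 0.1),
                                  rate = NULL, rest_duration = 100, seed = 1,
                                  band = c(0, 20)) {
  if (length(cv_grid) == 0)
    return(data.frame(cv = numeric(0), wi_predicted = numeric(0)))
  if (is.null(rate)) rate <- model$base_rate
  drive <- apply_transfer(model$linear, stimulus)
  fr <- predict_nonlinearity(model$nonlinearity, drive$values + model$base_rate)
  pfr <- power_spectrum(fr, sample_rate = stimulus$sample_rate,
                        window_s = model$settings$window_s,
                        n_tapers = model$settings$n_tapers)
  wi <- vapply(seq_along(cv_grid), function(i) {
    rest <- generate_renewal_spiketrain(rate, cv_grid[i], rest_duration,
                                        seed = derive_seed(seed, paste0("cv", i)))
    p0 <- power_spectrum(rest, window_s = model$settings$window_s,
                         n_tapers = model$settings$n_tapers)
    pred <- spectral_estimate(pfr$freq, pfr$power + p0$power,
                              convention = "point_process")
    whitening_index(pred, band = band)$wi
  }, numeric(1))
  data.frame(cv = cv_grid, wi_predicted = wi)
}
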