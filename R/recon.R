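# Optimal linear (Wiener) stimulus reconstruction from one or two spike
# trains, and the coding fraction.

#' Settings for Wiener-kernel estimation
#'
#' @param window_s spectral window (s)
#' @param n_tapers sine tapers per window
#' @param max_lag_s half-width of the acausal kernel (s), default 0.3
#' @param band frequency band over which the kernel is solved (Hz); the
#'   frequency response is zero outside
#' @param taper_frac fraction of each kernel end cosine-tapered
#' @param overlap fractional window overlap of the spectral estimator
#' @param cond_threshold condition-number threshold triggering
#'   regularization of the paired solve
#' @return list of class `wiener_settings`
#' @export
wiener_settings <- function(window_s = 2.048, n_tapers = 4, max_lag_s = 0.3,
                            band = c(0, 30), taper_frac = 0.1,
                            overlap = 0.5, cond_threshold = 1e6) {
  structure(list(window_s = window_s, n_tapers = n_tapers,
                 max_lag_s = max_lag_s, band = band, taper_frac = taper_frac,
                 overlap = overlap, cond_threshold = cond_threshold),
            class = "wiener_settings")
}

# inverse-transform a one-sided frequency response (on the estimator grid)
# into an acausal time-domain kernel truncated to +/- max_lag, edge-tapered
kernel_from_response <- function(freq, Kf, fs, settings) {
  nf <- length(freq)
  nw <- (nf - 1L) * 2L
  full <- complex(length.out = nw)
  full[1] <- Kf[1]
  full[2:nf] <- Kf[2:nf]
  full[nw:(nf + 1L)] <- Conj(Kf[2:(nf - 1L)])
  k <- Re(stats::fft(full, inverse = TRUE)) * fs / nw
  L <- round(settings$max_lag_s * fs)
  L <- min(L, nw %/% 2 - 1L)
  vals <- c(k[(nw - L + 1L):nw], k[1:(L + 1L)])  # lags -L .. +L
  lags <- (-L:L) / fs
  ntap <- max(1L, round(settings$taper_frac * length(vals) / 2))
  w <- rep(1, length(vals))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(ntap) - 0.5) / ntap))
  w[seq_len(ntap)] <- ramp
  w[length(vals) + 1L - seq_len(ntap)] <- ramp
  structure(list(lag_s = lags, value = vals * w, sample_rate = fs),
            class = "recon_kernel")
}

#' Optimal reconstruction kernel for a single neuron
#'
#' Frequency-domain Wiener solution K(f) = P_RS*(f) / P_RR(f) (equivalently
#' the cross-spectrum from response to stimulus over the response
#' auto-spectrum), solved on the estimator grid, restricted to the settings
#' band, inverse-transformed and truncated to an acausal +/- `max_lag_s`
#' kernel with cosine-tapered edges. Convolving the zero-mean binary
#' sequence with this kernel minimizes the mean squared reconstruction
#' error among linear decoders.
#'
#' @param response a `spike_train` (or `trace`)
#' @param stimulus a `trace`
#' @param settings a [wiener_settings()]
#' @param segments optional seam boundaries from [mask_and_concatenate()]
#' @return a `recon_kernel` (data-frame-like: `lag_s`, `value`)
#' @export
optimal_kernel_single <- function(response, stimulus,
                                  settings = wiener_settings(),
                                  segments = NULL) {
  if (inherits(response, "spike_train") && length(response$times) == 0)
    stop("degenerate (empty) spike train")
  a <- rate_signal(response)
  b <- rate_signal(stimulus)
  est <- mt_csd(a$z, b$z, fs = a$fs, window_s = settings$window_s,
                n_tapers = settings$n_tapers, overlap = settings$overlap,
                segments = segments)
  Kf <- est$sxy / pmax(est$sxx, .Machine$double.xmin)
  # per-window demeaning leaves the DC bin uninformative; the kernel response
  # is continuous there, so extrapolate from the first resolved bin
  Kf[1] <- Re(Kf[2])
  Kf[est$freq < settings$band[1] | est$freq > settings$band[2]] <- 0
  kernel_from_response(est$freq, Kf, a$fs, settings)
}

#' Optimal reconstruction kernels for a neuron pair
#'
#' Per-frequency 2x2 solve of the cross-spectral matrix equation
#' `[P_RiRj] [K1 K2]' = [P_R1S P_R2S]'`. Ill-conditioned frequencies are
#' regularized by adding a small multiple of the mean diagonal (flagged);
#' identical trains make the matrix singular everywhere, in which case the
#' solve falls back to the single-neuron kernel with a warning.
#'
#' @param r1,r2 `spike_train`s on the same grid
#' @param stimulus a `trace`
#' @param settings a [wiener_settings()]
#' @param segments optional seam boundaries
#' @return list with `k1`, `k2` (`recon_kernel`s), `regularized` (fraction of
#'   bins), `fallback` (logical)
#' @export
optimal_kernel_pair <- function(r1, r2, stimulus,
                                settings = wiener_settings(),
                                segments = NULL) {
  a1 <- rate_signal(r1)
  a2 <- rate_signal(r2)
  b <- rate_signal(stimulus)
  if (identical(a1$z, a2$z)) {
    warning("identical spike trains: cross-spectral matrix singular, ",
            "falling back to the single-neuron kernel")
    k1 <- optimal_kernel_single(r1, stimulus, settings, segments)
    k0 <- k1
    k0$value <- 0 * k0$value
    return(list(k1 = k1, k2 = k0, regularized = 0, fallback = TRUE))
  }
  e11 <- mt_csd(a1$z, a2$z, fs = a1$fs, window_s = settings$window_s,
                n_tapers = settings$n_tapers, overlap = settings$overlap,
                segments = segments)
  e1s <- mt_csd(a1$z, b$z, fs = a1$fs, window_s = settings$window_s,
                n_tapers = settings$n_tapers, overlap = settings$overlap,
                segments = segments)
  e2s <- mt_csd(a2$z, b$z, fs = a1$fs, window_s = settings$window_s,
                n_tapers = settings$n_tapers, overlap = settings$overlap,
                segments = segments)
  S11 <- e11$sxx; S22 <- e11$syy; S12 <- e11$sxy
  b1 <- e1s$sxy; b2 <- e2s$sxy
  det <- S11 * S22 - Mod(S12)^2
  bad <- det < (S11 * S22) / settings$cond_threshold
  if (any(bad)) {
    eps <- 0.5 * (S11[bad] + S22[bad]) / sqrt(settings$cond_threshold)
    S11b <- S11[bad] + eps; S22b <- S22[bad] + eps
    det[bad] <- S11b * S22b - Mod(S12[bad])^2
    S11[bad] <- S11b; S22[bad] <- S22b
  }
  K1 <- (S22 * b1 - S12 * b2) / det
  K2 <- (S11 * b2 - Conj(S12) * b1) / det
  K1[1] <- Re(K1[2]); K2[1] <- Re(K2[2])
  sel <- e11$freq < settings$band[1] | e11$freq > settings$band[2]
  K1[sel] <- 0; K2[sel] <- 0
  list(k1 = kernel_from_response(e11$freq, K1, a1$fs, settings),
       k2 = kernel_from_response(e11$freq, K2, a1$fs, settings),
       regularized = mean(bad), fallback = FALSE)
}

#' Reconstruct the stimulus from spike trains and kernels
#'
#' S_rec(t) = sum_i (K_i * R_i)(t), where each R_i enters as its zero-mean
#' binary sequence (so the reconstruction is of the stimulus about its mean).
#' Samples within half a kernel window of the record edges or of a
#' concatenation seam are flagged invalid and excluded from scoring.
#'
#' @param responses a `spike_train`/`trace` or list of them
#' @param kernels a `recon_kernel` or list of them (one per response)
#' @param segments optional seam boundaries from [mask_and_concatenate()]
#' @return list with `reconstruction` (`trace`) and `valid` (logical vector)
#' @export
reconstruct <- function(responses, kernels, segments = NULL) {
  if (!is.list(responses) || inherits(responses, c("spike_train", "trace")))
    responses <- list(responses)
  if (inherits(kernels, "recon_kernel")) kernels <- list(kernels)
  stopifnot(length(responses) == length(kernels))
  a <- rate_signal(responses[[1]])
  n <- length(a$z)
  fs <- a$fs
  out <- numeric(n)
  for (i in seq_along(responses)) {
    ai <- rate_signal(responses[[i]])
    stopifnot(length(ai$z) == n)
    k <- kernels[[i]]
    L <- (length(k$value) - 1L) %/% 2L
    # FFT convolution; kernel centered at zero lag
    nfft <- stats::nextn(n + length(k$value), 2)
    kf <- numeric(nfft)
    kf[1:(L + 1L)] <- k$value[(L + 1L):(2L * L + 1L)]   # lags 0..L
    if (L > 0) kf[(nfft - L + 1L):nfft] <- k$value[1:L] # lags -L..-1
    conv <- Re(stats::fft(stats::fft(c(ai$z, numeric(nfft - n))) *
                            stats::fft(kf), inverse = TRUE)) / nfft
    out <- out + conv[1:n] / fs
  }
  Lmax <- max(vapply(kernels,
                     function(k) (length(k$value) - 1L) %/% 2L, 1L))
  valid <- rep(TRUE, n)
  half <- Lmax
  edge <- function(i0, i1) {
    lo <- max(1L, i0); hi <- min(n, i1)
    if (hi >= lo) valid[lo:hi] <<- FALSE
  }
  edge(1L, half)
  edge(n - half + 1L, n)
  if (!is.null(segments) && nrow(segments) > 1) {
    seams <- round(segments$start_s[-1] * fs)
    for (s0 in seams) {
      edge(s0 - half + 1L, s0 + half)
    }
  }
  list(reconstruction = trace(out, sample_rate = fs, unit = "deg/s"),
       valid = valid)
}

#' Coding fraction of a reconstruction
#'
#' CF = 1 - RMSE / sd(S), where the root-mean-squared error is computed
#' between the (mean-subtracted) stimulus and the reconstruction over valid
#' samples. CF = 1 for a perfect reconstruction and 0 when the
#' reconstruction does no better than the stimulus mean; it is the fraction
#' of stimulus variance correctly reconstructed.
#'
#' @param stimulus a `trace`
#' @param reconstruction a `trace` (zero-mean reconstruction)
#' @param valid logical vector of samples to score (default: all)
#' @param min_valid_s minimum valid data required (s), default 10
#' @return list with `cf`, `mse`, `n_valid`
#' @export
coding_fraction <- function(stimulus, reconstruction, valid = NULL,
                            min_valid_s = 10) {
  s <- stimulus$values - mean(stimulus$values)
  r <- reconstruction$values
  stopifnot(length(s) == length(r))
  if (is.null(valid)) valid <- rep(TRUE, length(s))
  if (sum(valid) < min_valid_s * stimulus$sample_rate)
    stop("fewer than ", min_valid_s, " s of valid samples")
  sig <- stats::sd(s[valid])
  if (sig == 0) stop("stimulus has zero variance: coding fraction undefined")
  mse <- mean((s[valid] - r[valid])^2)
  list(cf = 1 - sqrt(mse) / sig, mse = mse, n_valid = sum(valid))
}

#' Write a reconstruction kernel as `lag_s,value` delimited text
#' @param kernel a `recon_kernel`
#' @param path file path
#' @export
write_kernel <- function(kernel, path) {
  utils::write.csv(data.frame(lag_s = kernel$lag_s, value = kernel$value),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
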