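# Core containers: spike trains, uniformly sampled traces, spectral
# estimates, and segment masks, plus their plain-text readers/writers.

#' Construct a spike train
#'
#' Event times in seconds over a recording of known duration. Times must be
#' strictly increasing and lie in `[0, duration)`. The binarization grid
#' (default 1 kHz) is carried with the object so spectral code downstream
#' never has to guess it.
#'
#' @param times numeric vector of spike times (seconds)
#' @param duration recording duration (seconds)
#' @param sample_rate binarization grid (Hz)
#' @return an object of class `spike_train`
#' @export
spike_train <- function(times, duration, sample_rate = 1000) {
  times <- as.numeric(times)
  stopifnot(duration > 0, sample_rate > 0)
  if (length(times) > 0) {
    if (is.unsorted(times, strictly = TRUE))
      stop("spike times must be strictly increasing")
    if (times[1] < 0 || times[length(times)] >= duration)
      stop("spike times must lie in [0, duration)")
  }
  structure(list(times = times, duration = as.numeric(duration),
                 sample_rate = sample_rate),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3f s (%.1f sp/s), grid %g Hz\n",
              length(x$times), x$duration,
              length(x$times) / x$duration, x$sample_rate))
  invisible(x)
}

#' Construct a uniformly sampled trace
#'
#' @param values numeric samples
#' @param sample_rate sampling rate (Hz)
#' @param unit unit label (e.g. "deg/s")
#' @return an object of class `trace`
#' @export
trace <- function(values, sample_rate = 1000, unit = "deg/s") {
  stopifnot(is.numeric(values), length(values) > 0, sample_rate > 0)
  structure(list(values = as.numeric(values), sample_rate = sample_rate,
                 unit = unit),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz (%.3f s), unit %s, sd %.3f\n",
              length(x$values), x$sample_rate,
              length(x$values) / x$sample_rate, x$unit, stats::sd(x$values)))
  invisible(x)
}

#' Duration of a trace or spike train in seconds
#' @param x a `trace` or `spike_train`
#' @return seconds
#' @export
duration_s <- function(x) {
  if (inherits(x, "trace")) return(length(x$values) / x$sample_rate)
  if (inherits(x, "spike_train")) return(x$duration)
  stop("unsupported type")
}

#' Binarize a spike train onto its sampling grid
#'
#' Bin `t` covers `[t/fs, (t+1)/fs)`; the bin value is the spike count in
#' that bin (almost always 0/1 at 1 kHz, but counts are never clipped).
#'
#' @param train a `spike_train`
#' @return integer vector of per-bin counts
#' @export
binarize <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  n <- round(train$duration * train$sample_rate)
  if (length(train$times) == 0) return(integer(n))
  idx <- floor(train$times * train$sample_rate) + 1L
  idx[idx > n] <- n  # guard against times within rounding of duration
  tabulate(idx, nbins = n)
}

#' Construct a segment mask
#'
#' Half-open `[start, end)` intervals in seconds, sorted and non-overlapping.
#' Used both for exclusion (quick phases, saccades) and retention (eye in
#' window) depending on the consuming function.
#'
#' @param intervals two-column matrix or data.frame of `start_s`, `end_s`
#' @param label free-text label (e.g. "quick_phase")
#' @return an object of class `segment_mask`
#' @export
segment_mask <- function(intervals, label = "") {
  m <- as.matrix(intervals)
  if (length(m) == 0) m <- matrix(numeric(0), ncol = 2)
  stopifnot(ncol(m) == 2)
  if (nrow(m) > 0) {
    if (any(m[, 2] <= m[, 1])) stop("mask intervals must have end > start")
    o <- order(m[, 1])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2]))
      stop("mask intervals must be non-overlapping")
  }
  colnames(m) <- c("start_s", "end_s")
  structure(list(intervals = m, label = label), class = "segment_mask")
}

#' Total time covered by a mask
#' @param mask a `segment_mask`
#' @return seconds
#' @export
mask_duration <- function(mask) {
  stopifnot(inherits(mask, "segment_mask"))
  if (nrow(mask$intervals) == 0) return(0)
  sum(mask$intervals[, 2] - mask$intervals[, 1])
}

#' Complement of a mask within a recording
#' @param mask a `segment_mask`
#' @param duration recording duration (s)
#' @return a `segment_mask` covering everything outside `mask`
#' @export
mask_complement <- function(mask, duration) {
  iv <- mask$intervals
  edges <- c(0, as.vector(t(iv)), duration)
  out <- matrix(edges, ncol = 2, byrow = TRUE)
  out <- out[out[, 2] > out[, 1], , drop = FALSE]
  segment_mask(out, label = paste0("not_", mask$label))
}

#' Construct a spectral estimate
#'
#' One-sided frequency grid with non-negative power and estimator metadata.
#' For spike trains the power is a point-process spectral density in units of
#' sp^2/s (flat at the rate lambda for a Poisson train); for traces it is a
#' one-sided PSD in unit^2/Hz whose band integral recovers the variance.
#'
#' @param freq frequency grid (Hz, strictly increasing, one-sided)
#' @param power spectral density values (>= 0)
#' @param n_windows number of window x taper averages behind the estimate
#' @param resolution frequency resolution (Hz)
#' @param convention "point_process" or "trace"
#' @return an object of class `spectral_estimate`
#' @export
spectral_estimate <- function(freq, power, n_windows = NA_integer_,
                              resolution = NA_real_,
                              convention = "trace") {
  stopifnot(length(freq) == length(power))
  if (is.unsorted(freq, strictly = TRUE)) stop("freq must be strictly increasing")
  if (any(power < 0)) stop("power must be non-negative")
  structure(list(freq = as.numeric(freq), power = as.numeric(power),
                 n_windows = n_windows, resolution = resolution,
                 convention = convention),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectral_estimate> %d bins, %.3g-%.4g Hz, resolution %.3g Hz, %s convention, %s averages\n",
    length(x$freq), min(x$freq), max(x$freq), x$resolution, x$convention,
    ifelse(is.na(x$n_windows), "?", x$n_windows)))
  invisible(x)
}

#' Average power of a spectral estimate over a frequency band
#' @param est a `spectral_estimate`
#' @param band `c(lo, hi)` in Hz
#' @return mean power over the band (trapezoidal)
#' @export
band_power <- function(est, band) {
  sel <- est$freq >= band[1] & est$freq <= band[2]
  if (sum(sel) < 2) stop("band contains fewer than 2 frequency bins")
  trapz(est$freq[sel], est$power[sel]) / diff(range(est$freq[sel]))
}

# ---- plain-text I/O ---------------------------------------------------------

#' Write / read a trace as delimited text (`time_s,value` with header)
#' @param x a `trace`
#' @param path file path
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  tt <- (seq_along(x$values) - 1) / x$sample_rate
  utils::write.csv(data.frame(time_s = tt, value = x$values), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param unit unit label attached on read
#' @export
read_trace <- function(path, unit = "deg/s") {
  d <- utils::read.csv(path)
  fs <- 1 / stats::median(diff(d$time_s))
  trace(d$value, sample_rate = round(fs), unit = unit)
}

#' Write / read spike times, one float (seconds) per line
#' @param train a `spike_train`
#' @param path file path
#' @export
write_spikes <- function(train, path) {
  writeLines(format(train$times, digits = 12, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' @rdname write_spikes
#' @param duration recording duration (s); defaults to last spike + 1 ms
#' @param sample_rate binarization grid (Hz)
#' @export
read_spikes <- function(path, duration = NULL, sample_rate = 1000) {
  tt <- as.numeric(readLines(path))
  tt <- tt[!is.na(tt)]
  if (is.null(duration))
    duration <- if (length(tt)) max(tt) + 1 / sample_rate else 1
  spike_train(tt, duration, sample_rate)
}

#' Write / read a segment mask as `start_s,end_s` pairs
#' @param mask a `segment_mask`
#' @param path file path
#' @export
write_mask <- function(mask, path) {
  utils::write.csv(as.data.frame(mask$intervals), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @param label label attached on read
#' @export
read_mask <- function(path, label = "") {
  d <- utils::read.csv(path)
  segment_mask(as.matrix(d), label = label)
}

#' Write a spectral estimate as `freq_hz,power` with a metadata header
#' @param est a `spectral_estimate`
#' @param path file path
#' @export
write_spectral_estimate <- function(est, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# convention: %s", est$convention),
    sprintf("# n_windows: %s", est$n_windows),
    sprintf("# resolution_hz: %s", est$resolution),
    "freq_hz,power"), con)
  utils::write.table(data.frame(est$freq, est$power), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectral_estimate
#' @export
read_spectral_estimate <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- grep("^#", hdr, value = TRUE)
  gv <- function(key) sub(sprintf("^# %s: ", key), "", grep(key, meta, value = TRUE)[1])
  d <- utils::read.csv(path, comment.char = "#")
  spectral_estimate(d$freq_hz, d$power,
                    n_windows = suppressWarnings(as.integer(gv("n_windows"))),
                    resolution = suppressWarnings(as.numeric(gv("resolution_hz"))),
                    convention = gv("convention"))
}
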