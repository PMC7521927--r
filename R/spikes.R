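# Spike-train statistics and segment masking/concatenation.

#' Interspike-interval statistics of a spike train
#'
#' Variability is summarized by the coefficient of variation (CV), the
#' standard deviation to mean ratio of the interspike-interval distribution:
#' CV = 0 for clock-like firing, 1 for Poisson-like firing. The SD uses the
#' unbiased (n-1) denominator; the convention is recorded in the result.
#'
#' @param train a `spike_train`
#' @return list with `firing_rate` (sp/s), `cv`, `isis` (s), `n_spikes`,
#'   `sd_convention`
#' @export
isi_stats <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  n <- length(train$times)
  if (n < 3) stop("insufficient events: need >= 3 spikes for ISI statistics")
  isis <- diff(train$times)
  list(firing_rate = n / train$duration,
       cv = stats::sd(isis) / mean(isis),
       isis = isis, n_spikes = n, sd_convention = "unbiased")
}

#' Mask a trace or spike train and concatenate the retained segments
#'
#' Keeps only the data inside `keep` and abuts the retained segments in a new
#' time base (as when quick-phase epochs are removed and the remaining
#' slow-phase epochs concatenated). The returned boundary list locates each
#' retained segment in the new time base so spectral code never windows
#' across a seam.
#'
#' @param x a `trace` or `spike_train`
#' @param keep a `segment_mask` of intervals to retain
#' @return list with `data` (same type as `x`) and `segments`
#'   (data.frame `start_s`, `end_s` in the new time base)
#' @export
mask_and_concatenate <- function(x, keep) {
  stopifnot(inherits(keep, "segment_mask"))
  iv <- keep$intervals
  if (nrow(iv) == 0) stop("empty retained set")
  dur <- duration_s(x)
  if (any(iv[, 1] < 0) || any(iv[, 2] > dur + 1e-9))
    stop("mask extends beyond recording duration")

  fs <- x$sample_rate
  # snap interval edges to the sampling grid: sample i covers [(i-1)/fs, i/fs)
  i0 <- floor(iv[, 1] * fs + 1e-9) + 1L
  i1 <- floor(iv[, 2] * fs + 1e-9)
  nkeep <- pmax(i1 - i0 + 1L, 0L)
  if (sum(nkeep) == 0) stop("empty retained set")
  new_start <- cumsum(c(0L, nkeep[-length(nkeep)])) / fs
  segments <- data.frame(start_s = new_start, end_s = new_start + nkeep / fs)

  if (inherits(x, "trace")) {
    idx <- unlist(mapply(function(a, b) if (b >= a) a:b else integer(0),
                         i0, i1, SIMPLIFY = FALSE))
    out <- trace(x$values[idx], sample_rate = fs, unit = x$unit)
  } else if (inherits(x, "spike_train")) {
    pieces <- vector("list", nrow(iv))
    for (k in seq_len(nrow(iv))) {
      sel <- x$times >= (i0[k] - 1L) / fs & x$times < i1[k] / fs
      pieces[[k]] <- x$times[sel] - (i0[k] - 1L) / fs + new_start[k]
    }
    out <- spike_train(unlist(pieces), duration = sum(nkeep) / fs,
                       sample_rate = fs)
  } else stop("unsupported type")
  list(data = out, segments = segments)
}

#' Segments where the eye position stays inside a window
#'
#' Builds a retention mask of the epochs during which the (fixation) eye
#' position is confined within `± limit_deg`, for restricting analyses to a
#' fixed oculomotor state.
#'
#' @param eye_position a `trace` in degrees
#' @param limit_deg half-width of the window (deg), default 5
#' @return a `segment_mask` labelled "eye_in_window"
#' @export
eye_position_window_mask <- function(eye_position, limit_deg = 5) {
  stopifnot(inherits(eye_position, "trace"))
  inside <- abs(eye_position$values) <= limit_deg
  runs_to_mask(inside, eye_position$sample_rate, "eye_in_window")
}

#' Detect high-velocity transients with a simple velocity threshold
#'
#' A minimal quick-phase/saccade flagging helper: marks samples whose absolute
#' velocity exceeds `threshold`, pads each run by `pad_s`, and merges
#' overlapping runs. Deliberately simple and fully configurable; it does not
#' attempt to reproduce clinical saccade-detection pipelines.
#'
#' @param velocity a `trace` (deg/s)
#' @param threshold detection threshold (deg/s)
#' @param pad_s padding added to each side of a detected run (s)
#' @return a `segment_mask` labelled "quick_phase"
#' @export
detect_velocity_transients <- function(velocity, threshold = 80, pad_s = 0.005) {
  stopifnot(inherits(velocity, "trace"))
  fast <- abs(velocity$values) > threshold
  m <- runs_to_mask(fast, velocity$sample_rate, "quick_phase")
  iv <- m$intervals
  if (nrow(iv) == 0) return(m)
  dur <- duration_s(velocity)
  iv[, 1] <- pmax(iv[, 1] - pad_s, 0)
  iv[, 2] <- pmin(iv[, 2] + pad_s, dur)
  # merge overlaps created by padding
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= merged[nrow(merged), 2]) {
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[k, 2])
    } else merged <- rbind(merged, iv[k, ])
  }
  segment_mask(merged, label = "quick_phase")
}

# logical run-length vector -> mask of TRUE runs (sample i covers
# [(i-1)/fs, i/fs))
runs_to_mask <- function(flag, fs, label) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  iv <- cbind((starts[sel] - 1L) / fs, ends[sel] / fs)
  segment_mask(iv, label = label)
}
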