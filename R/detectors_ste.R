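# Short-time-energy (STE) detector: moving-RMS energy of the band-passed
# signal thresholded at epoch mean + k SD, with duration, merge-gap and
# rectified-peak-count criteria.

#' Centered moving RMS
#'
#' Element `i` is the RMS over a centered window of `window_s` seconds; at
#' the edges the window shrinks to what the signal covers.
#'
#' @param x numeric signal.
#' @param window_s window length in seconds (> 0).
#' @param sample_rate sampling rate in Hz.
#' @return numeric vector, same length as `x`.
#' @export
moving_rms <- function(x, window_s, sample_rate) {
  if (!is.numeric(window_s) || window_s <= 0) stop("window_s must be positive")
  n <- length(x)
  w <- max(1L, round(window_s * sample_rate))
  if (w >= n) stop("window must be shorter than the signal")
  moving_rms_cpp(as.numeric(x), as.integer(floor(w / 2)))
}

# runs of TRUE as a 2-column matrix of 0-based half-open [start, end)
bool_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(starts[r$values], ends[r$values])
}

# merge sorted [start, end) intervals whose gap is < gap samples
merge_runs <- function(runs, gap) {
  if (nrow(runs) < 2L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, 1] - out[nrow(out), 2] < gap) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], runs[i, 2])
    } else {
      out <- rbind(out, runs[i, ])
    }
  }
  out
}

# strict local maxima of x (plateaus credited to their leftmost sample)
local_maxima <- function(x) {
  d <- diff(x)
  which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
}

#' Run the STE detector on one band-passed channel
#'
#' Per epoch: the moving RMS of the filtered signal is thresholded at the
#' epoch mean plus `rms_threshold_sd` SD; supra-threshold runs are merged
#' when closer than `min_gap_s`, delineated outward to the crossings of the
#' secondary `boundary_sd` threshold, required to last `min_event_s`, and
#' retained only when the rectified signal shows at least `min_peaks` local
#' maxima above its mean plus `peak_threshold_sd` SD. Events abutting an
#' epoch boundary are merged in a post-pass.
#'
#' @param filtered band-passed signal (already restricted to
#'   `[band_low, band_high]`).
#' @param params an [ste_params()] object.
#' @param sample_rate sampling rate in Hz.
#' @param raw_band optional alternative signal for the rectified-peak
#'   criterion (defaults to `filtered`).
#' @return data frame with 0-based half-open `start`, `end` sample columns,
#'   sorted and non-overlapping.
#' @export
detect_ste_channel <- function(filtered, params, sample_rate, raw_band = NULL) {
  stopifnot(inherits(params, "ste_params"))
  n <- length(filtered)
  if (n == 0L) stop("empty signal")
  if (is.null(raw_band)) raw_band <- filtered
  ep_len <- round(params$epoch_s * sample_rate)
  if (ep_len > n) {
    warning("epoch longer than signal; using a single epoch covering the signal")
    ep_len <- n
  }
  gap <- round(params$min_gap_s * sample_rate)
  min_len <- round(params$min_event_s * sample_rate)
  starts <- seq(0L, n - 1L, by = ep_len)
  events <- matrix(numeric(0), ncol = 2)
  for (s0 in starts) {
    s1 <- min(s0 + ep_len, n)              # final epoch may be shorter
    idx <- (s0 + 1L):s1
    seg <- filtered[idx]
    rms <- moving_rms_cpp(seg, as.integer(floor(round(params$rms_window_s * sample_rate) / 2)))
    mu <- mean(rms); sdv <- stats::sd(rms)
    if (!is.finite(sdv) || sdv == 0) next
    thr <- mu + params$rms_threshold_sd * sdv
    runs <- bool_runs(rms > thr)
    if (nrow(runs) == 0L) next
    runs <- merge_runs(runs, gap)
    # delineate: walk each run's edges out to the secondary threshold
    runs <- extend_runs(runs, rms, mu + params$boundary_sd * sdv)
    runs <- merge_runs(runs, max(gap, 1L))
    runs <- runs[runs[, 2] - runs[, 1] >= min_len, , drop = FALSE]
    if (nrow(runs) == 0L) next
    # rectified-peak criterion over the epoch statistics
    rect <- abs(raw_band[idx])
    pthr <- mean(rect) + params$peak_threshold_sd * stats::sd(rect)
    pk <- local_maxima(rect)
    pk <- pk[rect[pk] > pthr]
    keep <- vapply(seq_len(nrow(runs)), function(i) {
      sum(pk > runs[i, 1] & pk <= runs[i, 2]) >= params$min_peaks
    }, TRUE)
    runs <- runs[keep, , drop = FALSE]
    if (nrow(runs)) events <- rbind(events, runs + s0)
  }
  if (nrow(events) > 1L) {
    events <- events[order(events[, 1]), , drop = FALSE]
    events <- merge_runs(events, gap)   # merge across epoch boundaries
  }
  data.frame(start = as.integer(events[, 1]), end = as.integer(events[, 2]))
}
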