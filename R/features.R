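#' Feature-image geometry
#'
#' The default geometry renders each event as 128 x 128 images spanning
#' 10-290 Hz and 570 ms (285 ms either side of the event center), i.e.
#' 2.1875 Hz and 4.4531 ms per pixel. The geometry scales coherently: a
#' 32 x 32 image over 10-80 Hz and +/-72 ms, or 224 x 224 over 10-500 Hz
#' and +/-500 ms, keep essentially the same per-pixel resolution.
#'
#' @param size image side in pixels (default 128).
#' @param freq_low,freq_high frequency span in Hz (default 10-290).
#' @param half_width_ms half window width in ms (default 285).
#' @param n_cycles Morlet/Gabor time-bandwidth constant (default 6 cycles).
#' @return object of class `image_geometry`.
#' @export
image_geometry <- function(size = 128L, freq_low = 10, freq_high = 290,
                           half_width_ms = 285, n_cycles = 6) {
  stopifnot(size >= 8, freq_low > 0, freq_high > freq_low, half_width_ms > 0)
  structure(list(size = as.integer(size), freq_low = freq_low,
                 freq_high = freq_high, half_width_ms = half_width_ms,
                 n_cycles = n_cycles,
                 hz_per_px = (freq_high - freq_low) / size,
                 ms_per_px = 2 * half_width_ms / size),
            class = "image_geometry")
}

#' Extract an event-centered signal window
#'
#' The window is centered on the midpoint of the event's `[start, end)`
#' interval, optionally shifted by `shift_ms`, and spans `half_width_ms`
#' either side; samples beyond the recording bounds are zero-padded and the
#' pad lengths recorded. The segment length is `2 * half_width_ms *
#' sample_rate / 1000` rounded to an even count.
#'
#' @param rec an `hfo_recording`.
#' @param event list or one-row data frame with `channel`, `start`, `end`.
#' @param half_width_ms half window width, ms.
#' @param shift_ms center shift, ms; must satisfy `|shift_ms| <=
#'   half_width_ms`.
#' @return object of class `event_window`: list with `segment`,
#'   `center_sample`, `pad_left`, `pad_right`, `shift_ms`, `sample_rate`.
#' @export
extract_window <- function(rec, event, half_width_ms = 285, shift_ms = 0) {
  if (abs(shift_ms) > half_width_ms) {
    stop("|shift_ms| cannot exceed half_width_ms")
  }
  fs <- rec$sample_rate
  x <- channel_signal(rec, event$channel)
  if (event$start < 0 || event$end > length(x)) stop("event outside recording")
  w <- round(half_width_ms * fs / 1000)
  center <- floor((event$start + event$end) / 2) + round(shift_ms * fs / 1000)
  lo <- center - w           # 0-based, inclusive
  hi <- center + w           # 0-based, exclusive; length 2w (even)
  pad_left <- max(0L, -lo)
  pad_right <- max(0L, hi - length(x))
  core <- x[(max(lo, 0L) + 1L):min(hi, length(x))]
  structure(list(segment = c(rep(0, pad_left), core, rep(0, pad_right)),
                 center_sample = center, pad_left = pad_left,
                 pad_right = pad_right, shift_ms = shift_ms,
                 sample_rate = fs),
            class = "event_window")
}

# linear interpolation of y at `size` evenly spaced bin centers
resample_columns <- function(y, size) {
  n <- length(y)
  pos <- ((seq_len(size) - 0.5) / size) * (n - 1) + 1
  i0 <- floor(pos); frac <- pos - i0
  i1 <- pmin(i0 + 1, n)
  y[i0] * (1 - frac) + y[i1] * frac
}

#' Time-frequency (scalogram) feature image
#'
#' Magnitude of a continuous Morlet/Gabor wavelet transform of the raw
#' window, evaluated at `size` linearly spaced frequencies across the
#' geometry's band (each row one frequency bin center, low frequencies at
#' the bottom row), time resampled to `size` columns, and min-max
#' normalized per image to [0, 1] (an all-constant window yields an
#' all-zero image).
#'
#' @param window an [extract_window()] result.
#' @param sample_rate sampling rate in Hz.
#' @param geometry an [image_geometry()].
#' @return object of class `feature_image`: list with `grid` (`size x size`
#'   matrix, row 1 the highest frequency), `kind = "time_frequency"`,
#'   `freq_axis` (Hz per row), `time_axis_ms`.
#' @export
time_frequency_image <- function(window, sample_rate,
                                 geometry = image_geometry()) {
  x <- window$segment
  n <- length(x)
  size <- geometry$size
  freqs <- geometry$freq_low +
    (seq_len(size) - 0.5) * (geometry$freq_high - geometry$freq_low) / size
  # degenerate guard: at least one cycle of the lowest analysis frequency
  # must fit (shorter geometries, e.g. 32 px / +/-72 ms, are legitimate even
  # though the low-frequency wavelets then outlast the window)
  if (n < sample_rate / freqs[1]) {
    stop("window too short for the lowest analysis frequency")
  }
  nfft <- 2^ceiling(log2(2 * n))
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  fgrid <- (seq_len(nfft) - 1) / nfft * sample_rate
  neg <- fgrid > sample_rate / 2
  mag <- matrix(0, size, size)
  for (k in seq_len(size)) {
    f0 <- freqs[k]
    sigma_t <- geometry$n_cycles / (2 * pi * f0)
    sigma_f <- 1 / (2 * pi * sigma_t)
    # analytic Morlet kernel in the frequency domain (positive freqs only)
    ker <- exp(-((fgrid - f0)^2) / (2 * sigma_f^2))
    ker[neg] <- 0
    coef <- stats::fft(xf * ker, inverse = TRUE)[seq_len(n)] / nfft
    row <- Mod(coef)
    mag[size - k + 1L, ] <- resample_columns(row, size)  # low freq at bottom
  }
  rng <- range(mag)
  grid <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1]) else
    matrix(0, size, size)
  structure(list(grid = grid, kind = "time_frequency",
                 freq_axis = rev(freqs),
                 time_axis_ms = 2 * geometry$half_width_ms),
            class = "feature_image")
}

#' Amplitude-coding feature image
#'
#' Encodes the raw waveform's instantaneous amplitude: the window is
#' resampled to `size` columns and normalized by its absolute maximum; in
#' each column, pixels fill outward from the midline over a number of rows
#' proportional to the normalized absolute amplitude, above the midline for
#' positive polarity and below for negative. The image is invariant to
#' positive rescaling of the signal; a zero signal leaves only the midline.
#'
#' @param window an [extract_window()] result.
#' @param geometry an [image_geometry()].
#' @return a `feature_image` with `kind = "amplitude_coding"`.
#' @export
amplitude_coding_image <- function(window, geometry = image_geometry()) {
  size <- geometry$size
  y <- resample_columns(window$segment, size)
  a <- max(abs(y))
  v <- if (a > 0) y / a else rep(0, size)
  grid <- matrix(0, size, size)
  mid_top <- size %/% 2L          # midline rows (grid row 1 = top)
  mid_bot <- mid_top + 1L
  half <- size %/% 2L - 1L
  for (t in seq_len(size)) {
    grid[mid_top, t] <- 1
    grid[mid_bot, t] <- 1
    nfill <- round(abs(v[t]) * half)
    if (nfill > 0) {
      if (v[t] > 0) grid[(mid_top - nfill):(mid_top - 1L), t] <- 1
      else grid[(mid_bot + 1L):(mid_bot + nfill), t] <- 1
    }
  }
  structure(list(grid = grid, kind = "amplitude_coding", freq_axis = NULL,
                 time_axis_ms = 2 * geometry$half_width_ms),
            class = "feature_image")
}

#' Time-domain augmentation of an event window
#'
#' Training-time augmentation: the window center is shifted by a uniform
#' draw from +/- `max_shift_ms` and the extracted segment is time-reversed
#' with probability 1/2. The shift re-extracts from the recording, so new
#' samples enter the window. Evaluation paths must not call this.
#'
#' @param rec an `hfo_recording`.
#' @param event event row (`channel`, `start`, `end`).
#' @param half_width_ms half window width, ms.
#' @param max_shift_ms maximum center shift, ms (default 50).
#' @return an `event_window` with extra fields `flipped` and `shift_ms`.
#' @export
augment_window <- function(rec, event, half_width_ms = 285, max_shift_ms = 50) {
  shift <- stats::runif(1, -max_shift_ms, max_shift_ms)
  win <- extract_window(rec, event, half_width_ms, shift_ms = shift)
  win$flipped <- stats::runif(1) < 0.5
  if (win$flipped) win$segment <- rev(win$segment)
  win
}
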