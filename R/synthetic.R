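#' Synthetic iEEG simulation settings
#'
#' Configures the ground-truth simulator: per-channel 1/f ("pink")
#' background noise with injected ripple-band oscillatory bursts
#' (Gaussian-windowed sinusoids), optional co-occurring biphasic
#' epileptiform spike transients, and broadband artifact bursts. Every
#' injected interval is recorded with its class, so detector sensitivity,
#' boundary accuracy and classifier separability are all measurable without
#' clinical data.
#'
#' Event amplitudes are specified as the RMS of the injected component over
#' its truth interval, in multiples of the broadband background RMS (an SNR
#' in the usual sense); the truth interval of an oscillatory event is the
#' plus/minus 3 sigma support of its Gaussian envelope.
#'
#' @param duration_s recording length in seconds.
#' @param sample_rate sampling rate in Hz (default 2000).
#' @param n_channels number of channels.
#' @param noise_exponent 1/f^alpha spectral exponent (default 1, pink).
#' @param noise_rms background RMS in physical units (default 10, a typical
#'   interictal iEEG scale in microvolts).
#' @param hfo_count total oscillatory events, assigned round-robin.
#' @param hfo_freq_range event frequency range in Hz (default 80-250).
#' @param hfo_duration_range_ms truth duration range, ms (default 30-100).
#' @param hfo_amplitude event RMS in multiples of background RMS.
#' @param spike_prob probability an oscillatory event co-occurs with a
#'   spike transient (making it a spkHFO).
#' @param spike_width_ms biphasic transient width, ms.
#' @param spike_amplitude spike peak in multiples of background RMS.
#' @param artifact_count broadband artifact bursts.
#' @param artifact_amplitude artifact RMS in multiples of background RMS.
#' @param artifact_duration_range_ms artifact duration range, ms.
#' @param seed integer RNG seed; the whole simulation is reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(duration_s = 60, sample_rate = 2000, n_channels = 4,
                       noise_exponent = 1, noise_rms = 10,
                       hfo_count = 20, hfo_freq_range = c(80, 250),
                       hfo_duration_range_ms = c(30, 100), hfo_amplitude = 6,
                       spike_prob = 0.4, spike_width_ms = 40,
                       spike_amplitude = 8,
                       artifact_count = 0, artifact_amplitude = 10,
                       artifact_duration_range_ms = c(20, 80),
                       seed = 1L) {
  stopifnot(duration_s > 0, sample_rate > 0, n_channels >= 1,
            hfo_count >= 0, artifact_count >= 0,
            spike_prob >= 0, spike_prob <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# 1/f^alpha noise via spectral shaping of seeded white noise, unit RMS
pink_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f)             # two-sided frequency index
  scale <- c(0, 1 / (f[-1]^(alpha / 2)))
  x <- Re(stats::fft(sp * scale, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# sample non-overlapping [start, end) intervals (samples) of given lengths,
# kept clear of the recording edges and `spacing` apart; rejection sampling
place_intervals <- function(lengths, n_samples, edge_margin, spacing) {
  avail <- n_samples - 2L * edge_margin
  if (any(lengths > avail) || sum(lengths + spacing) > avail) {
    stop("infeasible packing: too many events for the duration")
  }
  out <- matrix(0L, 0, 2)
  for (len in lengths) {
    placed <- FALSE
    for (try in 1:400) {
      s <- sample.int(avail - len, 1L) + edge_margin
      cand <- c(s, s + len)
      if (nrow(out) == 0L ||
          all(cand[2] + spacing <= out[, 1] | cand[1] >= out[, 2] + spacing)) {
        out <- rbind(out, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible packing: too many events for the duration")
  }
  out
}

#' Simulate a ground-truth-labelled iEEG recording
#'
#' Draws the per-channel background noise first and the event parameters
#' after, so a zero-event configuration with the same seed reproduces the
#' identical background (the injected component is then the difference of
#' the two simulations). Oscillatory events are Gaussian-windowed sinusoids
#' whose frequency, duration and phase are drawn per event and whose RMS
#' over the truth interval is calibrated to `hfo_amplitude` times the
#' background RMS; spike transients are first-derivative-of-Gaussian
#' biphasic waves added at the event center; artifacts are broadband
#' white-noise bursts under a raised-cosine envelope.
#'
#' @param config a [sim_config()].
#' @return list with `recording` (an `hfo_recording`) and `truth` (an
#'   `hfo_events` set with labels `spkHFO` / `non-spkHFO` / `artifact` and
#'   extra columns `freq`, `snr`).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sample_rate
  n <- round(config$duration_s * fs)
  nch <- config$n_channels
  with_local_seed(config$seed, {
    sigs <- matrix(0, nch, n)
    for (c in seq_len(nch)) {
      sigs[c, ] <- pink_noise(n, config$noise_exponent) * config$noise_rms
    }
    truth <- list()
    n_ev <- config$hfo_count + config$artifact_count
    if (n_ev > 0) {
      chan_of <- rep(seq_len(nch), length.out = n_ev)      # round-robin
      kinds <- c(rep("hfo", config$hfo_count),
                 rep("artifact", config$artifact_count))
      edge_margin <- round(1.25 * fs)      # clear of the edge-artifact seconds
      spacing <- round(0.3 * fs)           # well beyond any merge gap
      for (c in seq_len(nch)) {
        mine <- which(chan_of == c)
        if (!length(mine)) next
        durs <- integer(length(mine))
        for (j in seq_along(mine)) {
          rng_ms <- if (kinds[mine[j]] == "hfo") config$hfo_duration_range_ms
                    else config$artifact_duration_range_ms
          durs[j] <- round(stats::runif(1, rng_ms[1], rng_ms[2]) / 1000 * fs)
        }
        iv <- place_intervals(durs, n, edge_margin, spacing)
        for (j in seq_along(mine)) {
          k <- mine[j]
          s0 <- iv[j, 1]; s1 <- iv[j, 2]
          len <- s1 - s0
          tt <- (seq_len(len) - (len + 1) / 2) / fs        # centered time, s
          if (kinds[k] == "hfo") {
            freq <- stats::runif(1, config$hfo_freq_range[1], config$hfo_freq_range[2])
            sigma <- (len / fs) / 6                        # truth = +/- 3 sigma
            phase <- stats::runif(1, 0, 2 * pi)
            u <- exp(-tt^2 / (2 * sigma^2)) * sin(2 * pi * freq * tt + phase)
            u <- u / sqrt(mean(u^2)) * config$hfo_amplitude * config$noise_rms
            is_spk <- stats::runif(1) < config$spike_prob
            if (is_spk) {
              tau <- config$spike_width_ms / 1000 / 4
              spk <- -tt / tau * exp(0.5 - tt^2 / (2 * tau^2))
              u <- u + spk * config$spike_amplitude * config$noise_rms
            }
            sigs[c, (s0 + 1):s1] <- sigs[c, (s0 + 1):s1] + u
            truth[[length(truth) + 1]] <- data.frame(
              channel = sprintf("CH%02d", c), start = s0, end = s1,
              label = if (is_spk) "spkHFO" else "non-spkHFO",
              freq = freq, snr = config$hfo_amplitude)
          } else {
            env <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
            u <- stats::rnorm(len) * env
            u <- u / sqrt(mean(u^2)) * config$artifact_amplitude * config$noise_rms
            sigs[c, (s0 + 1):s1] <- sigs[c, (s0 + 1):s1] + u
            truth[[length(truth) + 1]] <- data.frame(
              channel = sprintf("CH%02d", c), start = s0, end = s1,
              label = "artifact", freq = NA_real_,
              snr = config$artifact_amplitude)
          }
        }
      }
    }
    rec <- from_array(sigs, fs, sprintf("CH%02d", seq_len(nch)))
    tr <- if (length(truth)) do.call(rbind, truth) else
      data.frame(channel = character(), start = integer(), end = integer(),
                 label = character(), freq = numeric(), snr = numeric())
    o <- order(tr$channel, tr$start)
    ev <- hfo_events(tr$channel[o], tr$start[o], tr$end[o], detector = "truth",
                     sample_rate = fs, label = tr$label[o],
                     params = unclass(config))
    ev$freq <- tr$freq[o]
    ev$snr <- tr$snr[o]
    list(recording = rec, truth = ev)
  })
}

#' Simulate labelled feature images for classifier tests
#'
#' Runs [simulate_recording()], extracts the event-centered window at every
#' truth interval and builds the two feature images, yielding
#' `(image, class)` pairs ready for [train_classifier()].
#'
#' @param config a [sim_config()].
#' @param geometry an [image_geometry()].
#' @return list with `x` (array `size x size x 2 x n`, channel 1 the
#'   time-frequency image, channel 2 the amplitude-coding image), `labels`
#'   (character), `events` (the truth set) and `recording`.
#' @export
simulate_labelled_features <- function(config, geometry = image_geometry()) {
  sim <- simulate_recording(config)
  tr <- sim$truth
  n <- nrow(tr)
  x <- array(0, c(geometry$size, geometry$size, 2L, n))
  for (i in seq_len(n)) {
    ev <- list(channel = tr$channel[i], start = tr$start[i], end = tr$end[i])
    win <- extract_window(sim$recording, ev,
                          half_width_ms = geometry$half_width_ms)
    x[, , 1, i] <- time_frequency_image(win, sim$recording$sample_rate,
                                        geometry)$grid
    x[, , 2, i] <- amplitude_coding_image(win, geometry)$grid
  }
  list(x = x, labels = tr$label, events = tr, recording = sim$recording)
}
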