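# MNI-style detector: wavelet-entropy baseline identification on the
# band-passed signal, with an empirical baseline-CDF energy threshold when
# enough baseline exists and an iteratively refitted gamma-CDF threshold
# otherwise.

#' Gamma-CDF threshold from a positive sample
#'
#' Fits a gamma distribution by maximum likelihood and returns its quantile
#' at the requested percentile. Fitting goes through `MASS::fitdistr` on the
#' mean-normalized sample (the shape is scale-invariant), with a
#' Newton-on-shape fallback for samples where the optimizer fails.
#'
#' @param values positive numeric sample (>= 30 values, nonzero variance).
#' @param percentile quantile to return, in (0, 100); 0 is allowed and
#'   returns 0 (the lower limit of every gamma quantile function).
#' @return numeric threshold.
#' @export
fit_gamma_threshold <- function(values, percentile) {
  if (percentile == 0) return(0)
  if (percentile < 0 || percentile >= 100) stop("percentile must lie in [0, 100)")
  values <- values[is.finite(values)]
  if (length(values) < 30L) stop("need at least 30 values for a gamma fit")
  if (any(values <= 0)) stop("gamma fit requires strictly positive values")
  if (stats::sd(values) == 0) stop("degenerate (constant) input")
  m <- mean(values)
  xs <- values / m
  fit <- tryCatch(
    MASS::fitdistr(xs, "gamma", lower = c(1e-8, 1e-8)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    shape <- fit$estimate[["shape"]]
    rate <- fit$estimate[["rate"]] / m
  } else {
    # profile-likelihood Newton iteration on the shape
    s <- log(mean(xs)) - mean(log(xs))
    k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
    for (i in 1:25) {
      k <- k - (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
      if (!is.finite(k) || k <= 0) { k <- 1; break }
    }
    shape <- k
    rate <- k / m
  }
  stats::qgamma(percentile / 100, shape = shape, rate = rate)
}

# Wavelet (Gabor) entropy of a segment's autocorrelation spectrum: the
# segment's power spectrum (the Fourier transform of its autocorrelation)
# is projected onto a bank of Gaussian Gabor kernels spanning the analysis
# band in one matrix multiplication; the Shannon entropy of the normalized
# per-scale energies is returned. Near-white segments spread energy across
# scales (entropy near log(n_scales)); oscillations concentrate it.
gabor_entropy_bank <- function(nfft, sample_rate, band_low, band_high,
                               n_scales, n_cycles = 6) {
  freqs <- exp(seq(log(band_low), log(band_high), length.out = n_scales))
  fgrid <- (seq_len(nfft) - 1) / nfft * sample_rate
  half <- fgrid > sample_rate / 2
  fgrid[half] <- sample_rate - fgrid[half]     # fold negative frequencies
  bank <- matrix(0, n_scales, nfft)
  for (s in seq_len(n_scales)) {
    sigma_f <- freqs[s] / n_cycles
    bank[s, ] <- exp(-((fgrid - freqs[s])^2) / (2 * sigma_f^2))
  }
  bank
}

# extend each [start, end) run outward to the crossings of the secondary
# threshold, staying inside [lo, hi) (0-based sample bounds on the trace)
extend_runs <- function(runs, trace, thr_b, lo = 0L, hi = length(trace)) {
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]
    while (a > lo && trace[a] > thr_b) a <- a - 1L
    b <- runs[i, 2]
    while (b < hi && trace[b + 1L] > thr_b) b <- b + 1L
    runs[i, ] <- c(a, b)
  }
  runs
}

segment_entropy <- function(seg, bank) {
  sp <- Mod(stats::fft(c(seg - mean(seg), rep(0, ncol(bank) - length(seg)))))^2
  e <- as.vector(bank %*% sp)
  tot <- sum(e)
  if (tot <= 0) return(Inf)  # flat/zero segment: maximally baseline-like
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Run the MNI-style detector on one raw channel
#'
#' The channel is band-passed to `[band_low, band_high]`, its moving-RMS
#' energy trace computed, and `segment_s` windows classified as baseline
#' when the wavelet entropy of their autocorrelation spectrum exceeds
#' `baseline_entropy_threshold` times the maximum entropy. With at least
#' `baseline_min_s` of baseline, the detection threshold is the
#' `cdf_percentile_baseline` percentile of the baseline energy values;
#' otherwise, per `epoch_s` block, a gamma distribution is fitted to the
#' energy samples (subsampled through the seeded generator when large),
#' supra-threshold stretches are emitted and removed, and the fit repeats
#' for `n_iterations` rounds. Events closer than `min_gap_s` are merged and
#' must last `min_event_s`. Identical input and seed give identical output.
#'
#' @param raw raw (unfiltered) signal vector.
#' @param params an [mni_params()] object.
#' @param sample_rate sampling rate in Hz.
#' @param seed integer seed for the detector's random draws.
#' @return data frame with 0-based half-open `start`, `end` columns.
#' @export
detect_mni_channel <- function(raw, params, sample_rate, seed = 0L) {
  stopifnot(inherits(params, "mni_params"))
  n <- length(raw)
  seg_len <- round(params$segment_s * sample_rate)
  if (n < seg_len) stop("signal shorter than one baseline segment")
  spec <- filter_spec(params$band_low, params$band_high,
                      sample_rate = sample_rate)
  coeffs <- design_bandpass(spec)
  filtered <- apply_zero_phase(raw, coeffs)
  energy <- moving_rms_cpp(filtered,
                           as.integer(floor(round(params$energy_window_s * sample_rate) / 2)))
  if (all(energy == 0)) return(data.frame(start = integer(), end = integer()))
  nfft <- 2^ceiling(log2(2 * seg_len))
  bank <- gabor_entropy_bank(nfft, sample_rate, params$band_low,
                             params$band_high, params$n_scales,
                             n_cycles = params$entropy_cycles)
  h_max <- log(params$n_scales)
  seg_starts <- seq(0L, n - seg_len, by = seg_len)
  is_base <- vapply(seg_starts, function(s0) {
    segment_entropy(filtered[(s0 + 1):(s0 + seg_len)], bank) >
      params$baseline_entropy_threshold * h_max
  }, TRUE)
  baseline_s <- sum(is_base) * seg_len / sample_rate
  events <- matrix(numeric(0), ncol = 2)
  min_len <- round(params$min_event_s * sample_rate)
  gap <- round(params$min_gap_s * sample_rate)
  if (baseline_s >= params$baseline_min_s) {
    base_idx <- unlist(lapply(seg_starts[is_base],
                              function(s0) (s0 + 1):(s0 + seg_len)))
    thr <- stats::quantile(energy[base_idx],
                           params$cdf_percentile_baseline / 100, names = FALSE)
    runs <- bool_runs(energy > thr)
    if (nrow(runs)) {
      thr_b <- stats::quantile(energy[base_idx],
                               params$boundary_percentile / 100, names = FALSE)
      events <- extend_runs(runs, energy, min(thr_b, thr))
    }
  } else {
    events <- with_local_seed(seed, {
      acc <- matrix(numeric(0), ncol = 2)
      ep_len <- round(params$epoch_s * sample_rate)
      for (e0 in seq(0L, n - 1L, by = ep_len)) {
        e1 <- min(e0 + ep_len, n)
        active <- rep(TRUE, e1 - e0)
        vals <- energy[(e0 + 1):e1]
        for (it in seq_len(params$n_iterations)) {
          pool <- vals[active & vals > 0]
          if (length(pool) < 30L) break
          if (length(pool) > 10000L) pool <- pool[sample.int(length(pool), 10000L)]
          thr <- tryCatch(
            fit_gamma_threshold(pool, params$cdf_percentile_iterative),
            error = function(e) NA_real_)
          if (!is.finite(thr)) break
          mask <- active & vals > thr
          runs <- bool_runs(mask)
          runs <- runs[runs[, 2] - runs[, 1] >= min_len, , drop = FALSE]
          if (nrow(runs) == 0L) break
          thr_b <- tryCatch(
            fit_gamma_threshold(pool, params$boundary_percentile),
            error = function(e) thr)
          runs <- extend_runs(runs, vals, min(thr_b, thr))
          runs <- merge_runs(runs, 1L)
          for (i in seq_len(nrow(runs))) {
            active[(runs[i, 1] + 1):runs[i, 2]] <- FALSE
          }
          acc <- rbind(acc, runs + e0)
        }
      }
      acc
    })
  }
  if (nrow(events) == 0L) return(data.frame(start = integer(), end = integer()))
  events <- events[order(events[, 1]), , drop = FALSE]
  events <- merge_runs(events, gap)
  events <- events[events[, 2] - events[, 1] >= min_len, , drop = FALSE]
  data.frame(start = as.integer(events[, 1]), end = as.integer(events[, 2]))
}
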