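#' STE detector parameters
#'
#' Short-time-energy detector settings. Defaults follow the classic
#' RMS-energy detector configuration used by mainstream HFO tooling: moving
#' RMS over 3 ms, events where the RMS exceeds the epoch mean plus 5 SD for
#' at least 6 ms, candidate runs closer than 10 ms merged, and at least 6
#' rectified-signal peaks above mean plus 3 SD required per event. Epoch
#' statistics are computed per 600 s epoch. `boundary_sd` sets the secondary
#' (lower) threshold used to delineate event boundaries around each
#' supra-threshold run; setting it equal to `rms_threshold_sd` reproduces
#' plain run boundaries.
#'
#' @param band_low,band_high analysis band in Hz.
#' @param epoch_s epoch length in seconds for threshold statistics.
#' @param rms_window_s moving-RMS window length in seconds.
#' @param rms_threshold_sd detection threshold, SD multiples above the mean.
#' @param boundary_sd boundary-delineation threshold, SD multiples.
#' @param min_event_s minimum event duration in seconds.
#' @param min_gap_s events closer than this gap (seconds) are merged.
#' @param peak_threshold_sd rectified-peak threshold, SD multiples.
#' @param min_peaks minimum number of supra-threshold rectified peaks.
#' @return object of class `ste_params`.
#' @export
ste_params <- function(band_low = 80, band_high = 500, epoch_s = 600,
                       rms_window_s = 3e-3, rms_threshold_sd = 5,
                       boundary_sd = 1, min_event_s = 6e-3, min_gap_s = 10e-3,
                       peak_threshold_sd = 3, min_peaks = 6) {
  vals <- list(band_low = band_low, band_high = band_high, epoch_s = epoch_s,
               rms_window_s = rms_window_s, rms_threshold_sd = rms_threshold_sd,
               boundary_sd = boundary_sd, min_event_s = min_event_s,
               min_gap_s = min_gap_s, peak_threshold_sd = peak_threshold_sd,
               min_peaks = min_peaks)
  if (any(vapply(vals, function(v) !is.numeric(v) || v <= 0, TRUE))) {
    stop("all STE parameters must be positive numbers")
  }
  if (min_gap_s >= epoch_s) stop("min_gap_s must be smaller than epoch_s")
  if (boundary_sd > rms_threshold_sd) stop("boundary_sd cannot exceed rms_threshold_sd")
  structure(vals, class = "ste_params")
}

#' MNI detector parameters
#'
#' Settings for the baseline/gamma-CDF detector: the signal is band-passed,
#' 125 ms segments whose autocorrelation wavelet entropy exceeds a fraction
#' of the theoretical maximum are declared baseline, and the event threshold
#' comes either from the empirical baseline energy CDF (when enough baseline
#' exists) or from an iteratively refitted gamma distribution of segment
#' energies. Randomness (energy subsampling before the gamma fit) draws from
#' a generator seeded per channel.
#'
#' @param band_low,band_high analysis band in Hz (default 80-450).
#' @param epoch_s block length (seconds) for the iterative branch.
#' @param segment_s baseline-scanning window length in seconds.
#' @param baseline_entropy_threshold baseline when the segment's wavelet
#'   entropy exceeds this fraction of the maximum entropy.
#' @param baseline_min_s minimum cumulative baseline (seconds) required to
#'   use the empirical-CDF branch.
#' @param cdf_percentile_baseline percentile (0-100) of the baseline energy
#'   CDF used as the detection threshold.
#' @param cdf_percentile_iterative percentile (0-100) of the fitted gamma
#'   CDF used in the iterative branch.
#' @param boundary_percentile secondary (lower) energy percentile used to
#'   delineate event boundaries around each supra-threshold run; a
#'   detection threshold this far into the distribution's tail truncates
#'   tapered events, so boundaries extend outward to this level. Set equal
#'   to the detection percentile to reproduce plain run boundaries.
#' @param n_iterations gamma refit rounds in the iterative branch.
#' @param min_event_s,min_gap_s minimum event duration / merge gap, seconds.
#' @param energy_window_s moving-RMS window for the energy trace, seconds.
#' @param n_scales number of wavelet scales for the entropy measure.
#' @param entropy_cycles time-bandwidth constant of the entropy bank's
#'   Gabor kernels; larger values sharpen frequency selectivity so
#'   oscillatory segments score distinctly low entropy.
#' @return object of class `mni_params`.
#' @export
mni_params <- function(band_low = 80, band_high = 450, epoch_s = 60,
                       segment_s = 0.125, baseline_entropy_threshold = 0.67,
                       baseline_min_s = 5, cdf_percentile_baseline = 99.99,
                       cdf_percentile_iterative = 95, n_iterations = 10,
                       boundary_percentile = 95,
                       min_event_s = 10e-3, min_gap_s = 10e-3,
                       energy_window_s = 10e-3, n_scales = 16,
                       entropy_cycles = 12) {
  if (cdf_percentile_baseline <= 0 || cdf_percentile_baseline >= 100 ||
      cdf_percentile_iterative <= 0 || cdf_percentile_iterative >= 100) {
    stop("CDF percentiles must lie in (0, 100)")
  }
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (baseline_entropy_threshold <= 0 || baseline_entropy_threshold >= 1) {
    stop("baseline_entropy_threshold must lie in (0, 1)")
  }
  structure(list(band_low = band_low, band_high = band_high, epoch_s = epoch_s,
                 segment_s = segment_s,
                 baseline_entropy_threshold = baseline_entropy_threshold,
                 baseline_min_s = baseline_min_s,
                 cdf_percentile_baseline = cdf_percentile_baseline,
                 cdf_percentile_iterative = cdf_percentile_iterative,
                 n_iterations = as.integer(n_iterations),
                 boundary_percentile = boundary_percentile,
                 min_event_s = min_event_s, min_gap_s = min_gap_s,
                 energy_window_s = energy_window_s,
                 n_scales = as.integer(n_scales),
                 entropy_cycles = entropy_cycles),
            class = "mni_params")
}

#' Load pipeline parameters from a YAML config
#'
#' The shared config holds optional `filter`, `ste`, `mni`, `simulate`,
#' `model` and `train` tables; each is passed to the matching constructor,
#' so unknown keys are rejected and omitted keys take their defaults.
#'
#' @param path YAML file path.
#' @return named list with any of `filter`, `ste`, `mni` (constructed
#'   objects) plus the remaining tables as lists.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$filter)) out$filter_args <- cfg$filter
  if (!is.null(cfg$ste)) out$ste <- do.call(ste_params, cfg$ste)
  if (!is.null(cfg$mni)) out$mni <- do.call(mni_params, cfg$mni)
  for (nm in setdiff(names(cfg), c("filter", "ste", "mni"))) out[[nm]] <- cfg[[nm]]
  out
}

# restore-on-exit seeded RNG scope, so detector randomness never leaks into
# or depends on the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable, order-independent per-channel hash used to derive worker seeds
channel_hash <- function(name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 1048576
  as.integer(h)
}
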