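#' Detect HFO events across all channels of a recording
#'
#' Channel-parallel orchestrator: every channel is filtered and scanned
#' independently, so the work distributes across `n_jobs` worker processes
#' with no shared state, and the result is identical for any `n_jobs`.
#' Each channel's random draws come from a seed derived deterministically
#' from the master seed and a stable hash of the channel name, so results
#' are also invariant to channel ordering.
#'
#' @param rec an `hfo_recording`.
#' @param detector `"ste"` or `"mni"`.
#' @param params an [ste_params()] or [mni_params()] object matching the
#'   detector (defaults to the detector's defaults).
#' @param n_jobs number of worker processes (>= 1). Forked workers are used
#'   where available; on platforms without fork the work runs serially,
#'   with identical results.
#' @param seed master integer seed (MNI randomness; ignored by STE).
#' @return An `hfo_events` set sorted by (channel, start), with attributes
#'   `detector`, `params` (fingerprint) and `channel_counts`.
#' @examples
#' \donttest{
#' sim <- simulate_recording(sim_config(duration_s = 12, n_channels = 1,
#'                                      hfo_count = 3, seed = 7))
#' det <- detect(sim$recording, "ste")
#' summarize_events(det)
#' }
#' @export
detect <- function(rec, detector = c("ste", "mni"), params = NULL,
                   n_jobs = 1L, seed = 1L) {
  detector <- match.arg(detector)
  if (n_jobs < 1L) stop("n_jobs must be >= 1")
  if (is.null(params)) {
    params <- if (detector == "ste") ste_params() else mni_params()
  }
  ok <- (detector == "ste" && inherits(params, "ste_params")) ||
        (detector == "mni" && inherits(params, "mni_params"))
  if (!ok) stop(sprintf("params do not match detector '%s'", detector))
  fs <- rec$sample_rate
  coeffs <- if (detector == "ste") {
    design_bandpass(filter_spec(params$band_low, params$band_high,
                                sample_rate = fs))
  } else NULL
  worker <- function(name) {
    x <- rec$signals[match(name, rec$channel_names), ]
    ch_seed <- (as.integer(seed) + channel_hash(name)) %% .Machine$integer.max
    ev <- if (detector == "ste") {
      detect_ste_channel(apply_zero_phase(x, coeffs), params, fs)
    } else {
      detect_mni_channel(x, params, fs, seed = ch_seed)
    }
    if (nrow(ev)) ev$channel <- name
    ev
  }
  chans <- rec$channel_names
  res <- if (n_jobs > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(chans, worker, mc.cores = n_jobs)
  } else {
    lapply(chans, worker)
  }
  err <- vapply(res, inherits, TRUE, what = "try-error")
  if (any(vapply(res, function(r) inherits(r, "condition"), TRUE)) || any(err)) {
    stop("channel worker failed")
  }
  res <- res[vapply(res, nrow, 0L) > 0L]
  if (length(res)) {
    all_ev <- do.call(rbind, res)
    o <- order(all_ev$channel, all_ev$start)
    ev <- hfo_events(all_ev$channel[o], all_ev$start[o], all_ev$end[o],
                     detector = detector, sample_rate = fs,
                     params = unclass(params))
  } else {
    ev <- hfo_events(detector = detector, sample_rate = fs,
                     params = unclass(params))
  }
  attr(ev, "detector") <- detector
  attr(ev, "channel_counts") <- table(factor(ev$channel, levels = sort(chans)))
  ev
}
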