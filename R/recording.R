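#' Multichannel EEG recording in physical units
#'
#' A recording couples a channels-by-samples signal matrix (in the physical
#' dimension the source file declares, conventionally microvolts) with its
#' sampling rate and unique channel names. All channels share one sampling
#' rate and one sample count; sample coordinates throughout the package are
#' 0-based and half-open, so a sample index `i` corresponds to time
#' `i / sample_rate` seconds.
#'
#' @param signals numeric matrix, channels x samples.
#' @param sample_rate sampling rate in Hz (positive scalar).
#' @param channel_names character vector of unique names, one per row.
#' @return An object of class `hfo_recording` with elements `signals`,
#'   `sample_rate`, `channel_names`, `n_samples`.
#' @examples
#' rec <- from_array(matrix(rnorm(8000), nrow = 2), 2000, c("A1", "A2"))
#' duration_s(rec)
#' @export
from_array <- function(signals, sample_rate, channel_names) {
  if (is.vector(signals)) signals <- matrix(signals, nrow = 1)
  if (!is.matrix(signals) || !is.numeric(signals)) {
    stop("`signals` must be a numeric channels x samples matrix")
  }
  if (length(channel_names) == 0L) stop("at least one channel is required")
  if (nrow(signals) != length(channel_names)) {
    stop(sprintf("%d signal rows but %d channel names",
                 nrow(signals), length(channel_names)))
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("`sample_rate` must be a positive scalar (Hz)")
  }
  rownames(signals) <- channel_names
  structure(
    list(signals = signals,
         sample_rate = as.numeric(sample_rate),
         channel_names = as.character(channel_names),
         n_samples = ncol(signals)),
    class = "hfo_recording")
}

#' @export
print.hfo_recording <- function(x, ...) {
  cat(sprintf("<hfo_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              length(x$channel_names), x$n_samples, x$sample_rate,
              duration_s(x)))
  cat("channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `hfo_recording`.
#' @return numeric scalar, `n_samples / sample_rate`.
#' @export
duration_s <- function(rec) rec$n_samples / rec$sample_rate

#' Extract one channel's signal
#' @param rec an `hfo_recording`.
#' @param channel channel name.
#' @return numeric vector of samples.
#' @export
channel_signal <- function(rec, channel) {
  i <- match(channel, rec$channel_names)
  if (is.na(i)) stop(sprintf("unknown channel '%s'", channel))
  rec$signals[i, ]
}

#' Derive a bipolar montage
#'
#' Each output channel is the sample-wise difference anode minus cathode,
#' named `"anode-cathode"`, the conventional re-reference for grid/strip and
#' depth iEEG contacts.
#'
#' @param rec an `hfo_recording`.
#' @param pairs list of length-2 character vectors `(anode, cathode)`, or a
#'   2-column character matrix.
#' @return A new `hfo_recording` with one channel per pair.
#' @export
make_bipolar <- function(rec, pairs) {
  if (is.matrix(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  if (length(pairs) == 0L) stop("at least one pair is required")
  sigs <- matrix(0, nrow = length(pairs), ncol = rec$n_samples)
  nms <- character(length(pairs))
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    if (length(p) != 2L) stop("each pair must have exactly two channel names")
    ia <- match(p[1], rec$channel_names)
    ic <- match(p[2], rec$channel_names)
    if (is.na(ia) || is.na(ic)) {
      stop(sprintf("unknown channel in pair (%s, %s)", p[1], p[2]))
    }
    sigs[k, ] <- rec$signals[ia, ] - rec$signals[ic, ]
    nms[k] <- paste0(p[1], "-", p[2])
  }
  from_array(sigs, rec$sample_rate, nms)
}
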