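#' Per-channel EDF calibration header
#'
#' EDF stores integer samples; the header declares, per channel, the physical
#' range `[v_min, v_max]` and the digital range `[d_min, d_max]` that realize
#' the affine digital-to-physical map.
#'
#' @param v_min,v_max physical range (e.g. microvolts); must differ.
#' @param d_min,d_max digital (integer) range; `d_max` must exceed `d_min`.
#' @return An object of class `calibration_info`.
#' @export
calibration_info <- function(v_min, v_max, d_min, d_max) {
  n <- length(v_min)
  stopifnot(length(v_max) == n, length(d_min) == n, length(d_max) == n)
  if (any(d_max <= d_min)) stop("invalid header: d_max must exceed d_min")
  if (any(v_max == v_min)) stop("invalid header: v_max must differ from v_min")
  structure(list(v_min = as.numeric(v_min), v_max = as.numeric(v_max),
                 d_min = as.numeric(d_min), d_max = as.numeric(d_max)),
            class = "calibration_info")
}

#' Convert digital samples to physical values
#'
#' Applies the affine calibration `v = R * d + O` with gain
#' `R = (v_max - v_min) / (d_max - d_min)` and offset
#' `O = v_min - R * d_min`, the same map mainstream EEG readers use. The map
#' is exact at both digital range endpoints. Note that an offset-free variant
#' (`v = R * d`) circulates in older tooling and yields a DC-shifted trace;
#' this package always includes the offset.
#'
#' @param d_raw numeric/integer vector of digital samples.
#' @param cal a `calibration_info` describing a single channel (length-1
#'   fields), or an index `which` selecting the channel.
#' @param which channel index into `cal` (default 1).
#' @return numeric vector of physical values.
#' @examples
#' cal <- calibration_info(-100, 100, -1000, 1000)
#' calibrate(c(-1000, 0, 500, 1000), cal)  # -100, 0, 50, 100
#' @export
calibrate <- function(d_raw, cal, which = 1L) {
  stopifnot(inherits(cal, "calibration_info"))
  vmin <- cal$v_min[which]; vmax <- cal$v_max[which]
  dmin <- cal$d_min[which]; dmax <- cal$d_max[which]
  if (dmax <= dmin) stop("invalid header: d_max must exceed d_min")
  r <- (vmax - vmin) / (dmax - dmin)
  o <- vmin - r * dmin
  r * as.numeric(d_raw) + o
}
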