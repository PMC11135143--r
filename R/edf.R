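# EDF / EDF+ continuous reading and writing.
#
# EDF stores a 256-byte fixed header, then 256 bytes of header per signal,
# then data records of interleaved little-endian int16 samples. Physical
# values are reconstructed with the affine calibration in calibrate().
# Only continuous recordings with a homogeneous sampling rate are supported;
# EDF+ annotation signals are skipped and EDF+D (discontinuous) files are
# rejected.

edf_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF field '%s' exceeds %d chars", x, width))
  formatC(x, width = -width, flag = " ")
}

# format a number so that it fits an 8-char ascii field and parses back
edf_num8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(x, digits = digits, format = "g", width = 1)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format number for EDF header")
}

#' Write a recording to an EDF file
#'
#' Digitizes each channel to 16-bit integers over a symmetric physical range
#' covering the channel's extrema (the range actually written to the header,
#' so reading the file back reproduces the signal to within one quantization
#' step). Record duration is 1 s when the sample count divides evenly into
#' whole seconds, otherwise a single record spanning the recording.
#'
#' @param rec an `hfo_recording`.
#' @param path output file path.
#' @param physical_dimension unit string written per channel (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dimension = "uV") {
  ns <- length(rec$channel_names)
  n <- rec$n_samples
  fs <- rec$sample_rate
  if (n %% fs == 0 && abs(fs - round(fs)) < 1e-9) {
    spr <- as.integer(round(fs)); nrec <- n %/% spr; rec_dur <- 1
  } else {
    spr <- n; nrec <- 1L; rec_dur <- n / fs
  }
  dig_max <- 32767; dig_min <- -32767
  pm <- numeric(ns)
  for (k in seq_len(ns)) {
    a <- max(abs(rec$signals[k, ]))
    if (a == 0) a <- 1
    # round the range up so the formatted header value still covers the data
    a_fmt <- as.numeric(edf_num8(a))
    while (a_fmt < a) a_fmt <- as.numeric(edf_num8(a * (1 + 1e-5)))
    pm[k] <- a_fmt
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_ascii("0", 8))
  wr(edf_ascii("X X X X", 80))
  wr(edf_ascii("Startdate 01-JAN-2000 X X X", 80))
  wr(edf_ascii("01.01.00", 8))
  wr(edf_ascii("00.00.00", 8))
  wr(edf_ascii(256 * (1 + ns), 8))
  wr(edf_ascii("EDF+C", 44))
  wr(edf_ascii(nrec, 8))
  wr(edf_ascii(edf_num8(rec_dur), 8))
  wr(edf_ascii(ns, 4))
  for (nm in rec$channel_names) wr(edf_ascii(nm, 16))
  for (k in seq_len(ns)) wr(edf_ascii("", 80))
  for (k in seq_len(ns)) wr(edf_ascii(physical_dimension, 8))
  for (k in seq_len(ns)) wr(edf_ascii(edf_num8(-pm[k]), 8))
  for (k in seq_len(ns)) wr(edf_ascii(edf_num8(pm[k]), 8))
  for (k in seq_len(ns)) wr(edf_ascii(dig_min, 8))
  for (k in seq_len(ns)) wr(edf_ascii(dig_max, 8))
  for (k in seq_len(ns)) wr(edf_ascii("", 80))
  for (k in seq_len(ns)) wr(edf_ascii(spr, 8))
  for (k in seq_len(ns)) wr(edf_ascii("", 32))
  # digitize: d = round(v / pm * dig_max), inverse of the calibration map
  dig <- matrix(0L, nrow = ns, ncol = n)
  for (k in seq_len(ns)) {
    dig[k, ] <- as.integer(round(rec$signals[k, ] / pm[k] * dig_max))
  }
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (k in seq_len(ns)) {
      writeBin(dig[k, idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ continuous recording
#'
#' Parses the header, reads the interleaved 16-bit records, and calibrates
#' each channel to physical units via [calibrate()] (gain and offset both
#' applied). EDF+ annotation signals are dropped; discontinuous (EDF+D)
#' layouts and channel subsets with heterogeneous sampling rates are
#' rejected. EDF+ annotations/discontinuity markers are otherwise ignored.
#'
#' @param path EDF file path.
#' @param channels optional character vector: subset (and order) of channels
#'   to return; unknown names are an error.
#' @return list with elements `recording` (an `hfo_recording`) and
#'   `calibration` (a `calibration_info` for the returned channels).
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    if (length(raw) < w) stop("malformed EDF header: truncated")
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (version != "0") stop("malformed EDF header: bad version field")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  reserved <- rd(44)
  if (grepl("EDF+D", reserved, fixed = TRUE)) {
    stop("unsupported layout: discontinuous EDF+D recordings are not supported")
  }
  nrec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1 || is.na(nrec) || is.na(rec_dur) || rec_dur <= 0) {
    stop("malformed EDF header")
  }
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- rdn(16); rdn(80); rdn(8)
  phys_min <- as.numeric(rdn(8)); phys_max <- as.numeric(rdn(8))
  dig_min <- as.numeric(rdn(8)); dig_max <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (!is.na(header_bytes) && header_bytes != 256 * (1 + ns)) {
    stop("malformed EDF header: inconsistent header size")
  }
  ann <- labels == "EDF Annotations"
  total_per_rec <- sum(spr)
  data <- readBin(con, "integer", n = nrec * total_per_rec, size = 2L,
                  signed = TRUE, endian = "little")
  if (length(data) < nrec * total_per_rec) stop("malformed EDF: truncated data")
  keep <- which(!ann)
  if (!is.null(channels)) {
    sel <- match(channels, labels[keep])
    if (anyNA(sel)) {
      stop(sprintf("unknown channel(s): %s",
                   paste(channels[is.na(sel)], collapse = ", ")))
    }
    keep <- keep[sel]
  }
  if (length(keep) == 0L) stop("no signal channels to read")
  if (length(unique(spr[keep])) != 1L) {
    stop("unsupported layout: channels have heterogeneous sampling rates")
  }
  fs <- spr[keep[1]] / rec_dur
  offs <- c(0L, cumsum(spr))  # sample offset of each signal inside a record
  sigs <- matrix(0, nrow = length(keep), ncol = nrec * spr[keep[1]])
  for (j in seq_along(keep)) {
    k <- keep[j]
    idx <- as.vector(outer(seq_len(spr[k]) + offs[k],
                           (seq_len(nrec) - 1L) * total_per_rec, "+"))
    if (dig_max[k] <= dig_min[k] || phys_max[k] == phys_min[k]) {
      stop("invalid header: degenerate calibration range")
    }
    cal_k <- calibration_info(phys_min[k], phys_max[k], dig_min[k], dig_max[k])
    sigs[j, ] <- calibrate(data[idx], cal_k)
  }
  cal <- calibration_info(phys_min[keep], phys_max[keep],
                          dig_min[keep], dig_max[keep])
  list(recording = from_array(sigs, fs, labels[keep]), calibration = cal)
}
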