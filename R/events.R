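#' Construct an HFO event set
#'
#' An event set is a data frame with one detected event per row: `channel`,
#' `start` and `end` (0-based half-open sample coordinates), `detector`, and
#' optional `label` (one of `"artifact"`, `"spkHFO"`, `"non-spkHFO"`) and
#' `prob` columns. The sampling rate and detector/parameter fingerprint ride
#' along as attributes so exported files are self-describing.
#'
#' @param channel character vector of channel names.
#' @param start,end integer sample coordinates, 0-based half-open.
#' @param detector detector name(s) (`"ste"`, `"mni"`, or `"truth"`).
#' @param sample_rate sampling rate in Hz.
#' @param label,prob optional per-event class labels and probabilities.
#' @param params optional named list fingerprinting the detector parameters.
#' @return data frame of class `hfo_events`.
#' @export
hfo_events <- function(channel = character(), start = integer(),
                       end = integer(), detector = character(0),
                       sample_rate = NA_real_, label = NULL, prob = NULL,
                       params = NULL) {
  n <- length(start)
  stopifnot(length(end) == n, length(channel) %in% c(1L, n) || n == 0L)
  if (n > 0 && any(end <= start)) stop("events must satisfy start < end")
  df <- data.frame(channel = as.character(rep_len(channel, n)),
                   start = as.integer(start), end = as.integer(end),
                   detector = if (length(detector)) rep_len(detector, n) else rep("", n),
                   stringsAsFactors = FALSE)
  df$label <- if (is.null(label)) rep(NA_character_, n) else rep_len(label, n)
  df$prob <- if (is.null(prob)) rep(NA_real_, n) else rep_len(prob, n)
  attr(df, "sample_rate") <- sample_rate
  attr(df, "params") <- params
  class(df) <- c("hfo_events", "data.frame")
  df
}

#' @export
print.hfo_events <- function(x, ...) {
  cat(sprintf("<hfo_events> %d event(s) on %d channel(s)",
              nrow(x), length(unique(x$channel))))
  fs <- attr(x, "sample_rate")
  if (!is.null(fs) && !is.na(fs)) cat(sprintf(" @ %g Hz", fs))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Per-channel event count summary
#'
#' @param events an `hfo_events` set (labelled or not).
#' @return data frame with one row per channel: `channel`, `total`,
#'   `artifact`, `spkHFO`, `non_spkHFO` counts (label columns are zero when
#'   no labels are present).
#' @export
summarize_events <- function(events) {
  chs <- sort(unique(events$channel))
  cnt <- function(ch, lab) sum(events$channel == ch & !is.na(events$label) &
                                 events$label == lab)
  data.frame(channel = chs,
             total = vapply(chs, function(ch) sum(events$channel == ch), 0L),
             artifact = vapply(chs, cnt, 0L, lab = "artifact"),
             spkHFO = vapply(chs, cnt, 0L, lab = "spkHFO"),
             non_spkHFO = vapply(chs, cnt, 0L, lab = "non-spkHFO"),
             stringsAsFactors = FALSE)
}

#' Export an event set
#'
#' Two containers are supported. `"csv"` writes the per-event table with a
#' JSON metadata header line (prefixed `#`, holding the sampling rate,
#' detector and parameter fingerprint) and, alongside it, a
#' `<path>.channels.csv` per-channel summary (total / artifact / spkHFO /
#' non-spkHFO counts). `"rds"` serializes the event set losslessly in one
#' file. Both reload with [read_events()], reproducing event coordinates and
#' labels exactly.
#'
#' @param events an `hfo_events` set.
#' @param path output file path.
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
export_events <- function(events, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  meta <- list(sample_rate = attr(events, "sample_rate"),
               params = attr(events, "params"))
  if (format == "rds") {
    saveRDS(events, path)
    return(invisible(path))
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write to '%s'", path)))
  writeLines(paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  utils::write.csv(as.data.frame(events), con, row.names = FALSE)
  close(con)
  utils::write.csv(summarize_events(events),
                   paste0(path, ".channels.csv"), row.names = FALSE)
  invisible(path)
}

#' Reload an exported event set
#' @param path file written by [export_events()].
#' @param format `"csv"` or `"rds"`; inferred from the extension by default.
#' @return the `hfo_events` set.
#' @export
read_events <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  }
  if (format == "rds") return(readRDS(path))
  first <- readLines(path, n = 1L)
  meta <- if (startsWith(first, "#")) {
    jsonlite::fromJSON(sub("^#", "", first))
  } else list(sample_rate = NA_real_, params = NULL)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(channel = "character"))
  ev <- hfo_events(df$channel, df$start, df$end, df$detector,
                   sample_rate = if (is.null(meta$sample_rate)) NA_real_
                                 else meta$sample_rate,
                   label = df$label, prob = df$prob, params = meta$params)
  ev
}
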