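#' Interval overlap ratio (intersection over union)
#'
#' `(min(end_a, end_b) - max(start_a, start_b)) / (max(end_a, end_b) -
#' min(start_a, start_b))`, clamped to 0 for disjoint intervals. Symmetric,
#' bounded in [0, 1], and equal to 1 exactly when the intervals coincide.
#'
#' @param a,b length-2 numeric vectors `(start, end)` with `start < end`.
#' @return overlap fraction in [0, 1].
#' @examples
#' overlap_ratio(c(0, 10), c(5, 15))  # 1/3
#' @export
overlap_ratio <- function(a, b) {
  if (a[2] <= a[1] || b[2] <= b[1]) stop("degenerate interval")
  inter <- min(a[2], b[2]) - max(a[1], b[1])
  if (inter <= 0) return(0)
  inter / (max(a[2], b[2]) - min(a[1], b[1]))
}

# maximum-cardinality bipartite matching via augmenting paths (Kuhn's
# algorithm); adj[[i]] lists the b-indices compatible with a-event i,
# ordered so higher-overlap pairs are explored first
kuhn_match <- function(adj, nb) {
  env <- new.env()
  env$match_b <- rep(NA_integer_, nb)
  aug <- function(i) {
    for (j in adj[[i]]) {
      if (!env$visited[j]) {
        env$visited[j] <- TRUE
        if (is.na(env$match_b[j]) || aug(env$match_b[j])) {
          env$match_b[j] <- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (i in seq_along(adj)) {
    env$visited <- rep(FALSE, nb)
    aug(i)
  }
  env$match_b
}

#' Match two event sets one-to-one by overlap ratio
#'
#' Per channel, finds a maximum-cardinality one-to-one matching among event
#' pairs whose overlap ratio reaches `threshold` ("exceeds" read
#' inclusively, so `threshold = 1` demands exact sample agreement). The
#' candidate pairs come from a two-pointer sweep over the sorted
#' non-overlapping intervals of each set; the matching itself is computed
#' with augmenting-path search, exploring higher-overlap pairs first.
#'
#' @param set_a,set_b `hfo_events` sets (per-channel non-overlapping).
#' @param threshold overlap-ratio threshold in (0, 1].
#' @return An object of class `hfo_matching`: list with `pairs` (data frame
#'   `index_a`, `index_b`, `ratio` of row indices into the two sets),
#'   `unmatched_a`, `unmatched_b` (row indices), and `threshold`.
#' @export
match_events <- function(set_a, set_b, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  chans <- union(unique(set_a$channel), unique(set_b$channel))
  only_a <- setdiff(unique(set_a$channel), unique(set_b$channel))
  only_b <- setdiff(unique(set_b$channel), unique(set_a$channel))
  if (length(only_a) || length(only_b)) {
    warning("channels present in only one set are left unmatched")
  }
  pairs <- data.frame(index_a = integer(), index_b = integer(),
                      ratio = numeric())
  for (ch in chans) {
    ia <- which(set_a$channel == ch)
    ib <- which(set_b$channel == ch)
    if (!length(ia) || !length(ib)) next
    ia <- ia[order(set_a$start[ia])]
    ib <- ib[order(set_b$start[ib])]
    # two-pointer sweep collecting threshold-passing candidate pairs
    adj <- vector("list", length(ia))
    lo <- 1L
    for (u in seq_along(ia)) {
      a_iv <- c(set_a$start[ia[u]], set_a$end[ia[u]])
      while (lo <= length(ib) && set_b$end[ib[lo]] <= a_iv[1]) lo <- lo + 1L
      v <- lo
      cand <- numeric(0); ratios <- numeric(0)
      while (v <= length(ib) && set_b$start[ib[v]] < a_iv[2]) {
        r <- overlap_ratio(a_iv, c(set_b$start[ib[v]], set_b$end[ib[v]]))
        if (threshold < 1 && r >= threshold) {
          cand <- c(cand, v); ratios <- c(ratios, r)
        } else if (threshold == 1 &&
                   set_a$start[ia[u]] == set_b$start[ib[v]] &&
                   set_a$end[ia[u]] == set_b$end[ib[v]]) {
          cand <- c(cand, v); ratios <- c(ratios, 1)
        }
        v <- v + 1L
      }
      adj[[u]] <- cand[order(-ratios)]
    }
    mb <- kuhn_match(adj, length(ib))
    for (j in which(!is.na(mb))) {
      u <- mb[j]
      pairs <- rbind(pairs, data.frame(
        index_a = ia[u], index_b = ib[j],
        ratio = overlap_ratio(c(set_a$start[ia[u]], set_a$end[ia[u]]),
                              c(set_b$start[ib[j]], set_b$end[ib[j]]))))
    }
  }
  pairs <- pairs[order(pairs$index_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(nrow(set_a)), pairs$index_a),
                 unmatched_b = setdiff(seq_len(nrow(set_b)), pairs$index_b),
                 threshold = threshold),
            class = "hfo_matching")
}

#' @export
print.hfo_matching <- function(x, ...) {
  cat(sprintf("<hfo_matching> %d pair(s) at threshold %.2f; %d + %d unmatched\n",
              nrow(x$pairs), x$threshold,
              length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Discrepancy statistic between a reference and a comparison event set
#'
#' `new_r` and `new_p` count the events of each set left unmatched; the
#' discrepancy ratio is their sum over the reference set's size.
#'
#' @param set_r reference `hfo_events` set.
#' @param set_p comparison `hfo_events` set.
#' @param matching an `hfo_matching` computed from these two sets.
#' @return list `new_r`, `new_p`, `ratio`.
#' @export
discrepancy <- function(set_r, set_p, matching) {
  if (nrow(set_r) == 0L) stop("discrepancy undefined for an empty reference set")
  new_r <- nrow(set_r) - nrow(matching$pairs)
  new_p <- nrow(set_p) - nrow(matching$pairs)
  list(new_r = new_r, new_p = new_p, ratio = (new_r + new_p) / nrow(set_r))
}

#' Concordance report between two event sets
#'
#' Per channel and overall: totals, matched counts at exact / 0.9 / 0.5
#' overlap (or any requested thresholds), and the unmatched counts of each
#' set at the last threshold.
#'
#' @param set_a,set_b `hfo_events` sets.
#' @param thresholds overlap thresholds; `1` means exact sample agreement.
#' @return data frame, one row per channel plus a `TOTAL` row.
#' @export
compare_events <- function(set_a, set_b, thresholds = c(1, 0.9, 0.5)) {
  chans <- sort(union(unique(set_a$channel), unique(set_b$channel)))
  rows <- lapply(c(chans, "TOTAL"), function(ch) {
    if (ch == "TOTAL") { sa <- set_a; sb <- set_b }
    else {
      sa <- set_a[set_a$channel == ch, , drop = FALSE]
      sb <- set_b[set_b$channel == ch, , drop = FALSE]
    }
    row <- data.frame(channel = ch, total_a = nrow(sa), total_b = nrow(sb))
    for (th in thresholds) {
      m <- suppressWarnings(match_events(sa, sb, th))
      lab <- if (th == 1) "exact" else sprintf("overlap_%g", th)
      row[[lab]] <- nrow(m$pairs)
      row$new_a <- nrow(sa) - nrow(m$pairs)
      row$new_b <- nrow(sb) - nrow(m$pairs)
    }
    row
  })
  do.call(rbind, rows)
}
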