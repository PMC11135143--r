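# Shared fixtures and independent oracles, all built in code at test time.

FS <- 2000

# random per-channel-disjoint event set on [0, span)
random_event_set <- function(n_max = 10, span = 400, channel = "C") {
  n <- sample(0:n_max, 1)
  if (n == 0) return(hfo_events(sample_rate = FS))
  cuts <- sort(sample(0:span, 2 * n))
  st <- cuts[seq(1, 2 * n, 2)]
  en <- cuts[seq(2, 2 * n, 2)] + 1L
  hfo_events(channel, st, en, sample_rate = FS)
}

# exhaustive maximum bipartite matching size via bitmask DP over set B
brute_force_match_count <- function(sa, sb, threshold) {
  n <- nrow(sa); m <- nrow(sb)
  if (n == 0 || m == 0) return(0L)
  ok <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    r <- overlap_ratio(c(sa$start[i], sa$end[i]), c(sb$start[j], sb$end[j]))
    ok[i, j] <- if (threshold < 1) r >= threshold else
      sa$start[i] == sb$start[j] && sa$end[i] == sb$end[j]
  }
  memo <- new.env(hash = TRUE)
  rec <- function(i, used) {
    if (i > n) return(0L)
    key <- paste0(i, ":", used)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i + 1L, used)
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (ok[i, j] && bitwAnd(used, bit) == 0L) {
        best <- max(best, 1L + rec(i + 1L, bitwOr(used, bit)))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 0L)
}

# small separable two-class image set built directly (bright blob vs noise)
tiny_image_set <- function(n_per_class = 40, size = 32, seed = 99) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(stats::runif(size * size * n, 0, 0.3), c(size, size, 1, n))
    y <- rep(c("neg", "pos"), each = n_per_class)
    for (i in which(y == "pos")) {
      r0 <- sample(5:(size - 12), 1); c0 <- sample(5:(size - 12), 1)
      x[r0:(r0 + 6), c0:(c0 + 6), 1, i] <- x[r0:(r0 + 6), c0:(c0 + 6), 1, i] + 0.7
    }
    list(x = x, y = y)
  })
}

tiny_model_spec <- function(channels = 1L) {
  model_spec(input_channels = channels, input_size = 32L,
             conv_widths = c(4L, 8L), head = 8L)
}

tiny_train_config <- function(epochs = 12L, seed = 2L) {
  train_config(epochs = epochs, batch_size = 16L, learning_rate = 3e-3,
               seed = seed)
}

# memoized heavy fixtures shared across test files
.fixtures <- new.env()

detector_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_recording(
      sim_config(duration_s = 60, n_channels = 4, hfo_count = 20,
                 hfo_amplitude = 6, artifact_count = 0, seed = 42))
  }
  .fixtures$sim
}

detector_noise_sim <- function() {
  if (is.null(.fixtures$noise)) {
    .fixtures$noise <- simulate_recording(
      sim_config(duration_s = 60, n_channels = 4, hfo_count = 0,
                 artifact_count = 0, seed = 42))
  }
  .fixtures$noise
}

# labelled feature set under the study conditions (artifact vs real HFO)
separable_features <- function() {
  if (is.null(.fixtures$feats)) {
    cfg <- sim_config(duration_s = 40, n_channels = 4, hfo_count = 126,
                      artifact_count = 126, hfo_amplitude = 6,
                      spike_prob = 0.5, seed = 11)
    .fixtures$feats <- simulate_labelled_features(cfg)
  }
  .fixtures$feats
}

boundary_errors_ms <- function(truth, detected, matching, fs = FS) {
  errs <- numeric(0)
  for (r in seq_len(nrow(matching$pairs))) {
    i <- matching$pairs$index_a[r]; j <- matching$pairs$index_b[r]
    errs <- c(errs, abs(truth$start[i] - detected$start[j]),
              abs(truth$end[i] - detected$end[j]))
  }
  errs / fs * 1000
}

python_available <- function() {
  nzchar(Sys.which("python"))
}
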