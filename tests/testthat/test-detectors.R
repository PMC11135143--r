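test_that("moving RMS matches closed forms", {
  expect_equal(moving_rms(rep(-3, 100), 0.01, 1000), rep(3, 100))
  expect_equal(moving_rms(rep(0, 50), 0.01, 1000), rep(0, 50))
  # unit sine over an integer number of periods: RMS ~ 1/sqrt(2) off-edge
  x <- sin(2 * pi * 50 * (0:999) / 1000)  # 50 Hz at 1 kHz, window = 2 periods
  r <- moving_rms(x, 0.04, 1000)
  expect_equal(r[100:900], rep(1 / sqrt(2), 801), tolerance = 1e-2)
  expect_error(moving_rms(x, -1, 1000), "positive")
  expect_error(moving_rms(x, 2, 1000), "shorter")
})

test_that("STE finds injected bursts, honours the merge rule, and returns ordered events", {
  p <- ste_params(epoch_s = 10)
  withr::with_seed(21, {
    n <- 10 * FS
    noise <- rnorm(n, sd = 0.5)
    burst <- function(at_s, dur_s = 0.08, f = 120, amp = 8 * 0.5) {
      tt <- seq(0, dur_s, by = 1 / FS)
      idx <- round(at_s * FS) + seq_along(tt)
      list(idx = idx, w = amp * sin(2 * pi * f * tt) *
             exp(-((tt - dur_s / 2)^2) / (2 * (dur_s / 6)^2)))
    }
    x <- noise
    b1 <- burst(3); x[b1$idx] <- x[b1$idx] + b1$w
    ev1 <- detect_ste_channel(x, p, FS)
    expect_equal(nrow(ev1), 1)
    expect_gte(overlap_ratio(c(ev1$start, ev1$end),
                             c(min(b1$idx) - 1, max(b1$idx))), 0.5)
    # two bursts 2 s apart stay distinct
    x2 <- noise
    b2 <- burst(6)
    x2[b1$idx] <- x2[b1$idx] + b1$w; x2[b2$idx] <- x2[b2$idx] + b2$w
    expect_equal(nrow(detect_ste_channel(x2, p, FS)), 2)
    # two bursts closer than min_gap merge into one
    x3 <- noise
    b3 <- burst(3.085)
    x3[b1$idx] <- x3[b1$idx] + b1$w; x3[b3$idx] <- x3[b3$idx] + b3$w
    ev3 <- detect_ste_channel(x3, ste_params(epoch_s = 10, min_gap_s = 0.05), FS)
    expect_equal(nrow(ev3), 1)
  })
  expect_equal(nrow(suppressWarnings(detect_ste_channel(rep(0, 2000), p, FS))), 0)
  expect_error(detect_ste_channel(numeric(0), p, FS), "empty")
  expect_warning(detect_ste_channel(rnorm(1000), ste_params(), FS), "single epoch")
})

test_that("STE per-channel events are sorted, non-overlapping and >= minimum duration", {
  sim <- detector_sim()
  ev <- suppressWarnings(detect(sim$recording, "ste"))
  p <- ste_params()
  for (ch in unique(ev$channel)) {
    e <- ev[ev$channel == ch, ]
    expect_true(all(diff(e$start) > 0))
    expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
    expect_true(all(e$end - e$start >= round(p$min_event_s * FS)))
  }
})

test_that("STE is equivariant to amplitude scale and robust to DC offsets", {
  sim <- detector_sim()
  base <- suppressWarnings(detect(sim$recording, "ste"))
  scaled <- sim$recording
  scaled$signals <- scaled$signals * 7.3
  ev_s <- suppressWarnings(detect(scaled, "ste"))
  expect_equal(as.data.frame(ev_s), as.data.frame(base))
  shifted <- sim$recording
  shifted$signals <- shifted$signals + 500
  ev_d <- suppressWarnings(detect(shifted, "ste"))
  expect_equal(as.data.frame(ev_d), as.data.frame(base))
})

test_that("raising the STE threshold never increases the event count", {
  sim <- detector_sim()
  x <- channel_signal(sim$recording, "CH01")
  fil <- design_bandpass(filter_spec(80, 500, sample_rate = FS))
  xf <- apply_zero_phase(x, fil)
  counts <- vapply(c(3, 4, 5, 6, 8), function(k) {
    nrow(suppressWarnings(
      detect_ste_channel(xf, ste_params(rms_threshold_sd = k, boundary_sd = 1), FS)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("gamma threshold estimation matches the analytic exponential quantile", {
  withr::with_seed(4, {
    v <- rexp(100000)
    expect_equal(fit_gamma_threshold(v, 95), -log(0.05), tolerance = 0.02)
    # monotone in the percentile
    th <- vapply(c(50, 80, 95, 99), function(p) fit_gamma_threshold(v, p), 0)
    expect_true(all(diff(th) > 0))
    expect_equal(fit_gamma_threshold(v, 0), 0)
  })
  expect_error(fit_gamma_threshold(rep(1, 100), 95), "degenerate")
  expect_error(fit_gamma_threshold(c(-1, rexp(99)), 95), "positive")
  expect_error(fit_gamma_threshold(rexp(10), 95), "at least 30")
})

test_that("MNI is reproducible from its seed and silent on zero signals", {
  sim <- detector_sim()
  x <- channel_signal(sim$recording, "CH02")
  a <- detect_mni_channel(x, mni_params(), FS, seed = 9)
  b <- detect_mni_channel(x, mni_params(), FS, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(detect_mni_channel(rep(0, 30 * FS), mni_params(), FS)), 0)
  expect_error(detect_mni_channel(rnorm(100), mni_params(), FS), "shorter")
})

test_that("MNI's iterative gamma branch fires on channels with no usable baseline", {
  # continuous ripple background (no high-entropy baseline anywhere) with
  # five much stronger bursts that the gamma-CDF threshold should isolate
  withr::with_seed(8, {
    t <- (0:(30 * FS - 1)) / FS
    x <- sin(2 * pi * 140 * t) + rnorm(length(t), sd = 0.3)
    burst_at <- c(5, 11, 17, 23, 28)
    truth <- matrix(0L, length(burst_at), 2)
    for (k in seq_along(burst_at)) {
      idx <- round(burst_at[k] * FS) + 1:round(0.08 * FS)
      x[idx] <- x[idx] + 5 * sin(2 * pi * 160 * (idx / FS)) *
        exp(-((seq_along(idx) - 80)^2) / (2 * 27^2))
      truth[k, ] <- c(min(idx) - 1L, max(idx))
    }
    p <- mni_params(baseline_min_s = 1e6)  # force the iterative branch
    ev <- detect_mni_channel(x, p, FS, seed = 3)
    expect_gt(nrow(ev), 0)
    expect_true(all(ev$end - ev$start >= round(p$min_event_s * FS)))
    # every injected burst is recovered at overlap >= 0.5
    for (k in seq_along(burst_at)) {
      ious <- vapply(seq_len(nrow(ev)), function(j)
        overlap_ratio(truth[k, ], c(ev$start[j], ev$end[j])), 0)
      expect_gte(max(ious), 0.5)
    }
    ev2 <- detect_mni_channel(x, p, FS, seed = 3)
    expect_identical(ev, ev2)
  })
})

test_that("MNI recovers most high-SNR injections with accurate boundaries", {
  sim <- detector_sim()
  one <- sim$truth[sim$truth$channel == "CH01", ]
  x <- channel_signal(sim$recording, "CH01")
  ev <- detect_mni_channel(x, mni_params(), FS, seed = 1)
  ev_set <- hfo_events("CH01", ev$start, ev$end, sample_rate = FS)
  m <- match_events(one, ev_set, 0.5)
  expect_gte(nrow(m$pairs), ceiling(0.8 * nrow(one)))
  expect_lte(median(boundary_errors_ms(one, ev_set, m)), 10)
})

test_that("the orchestrator is invariant to n_jobs and channel order and composes per channel", {
  sim <- detector_sim()
  e1 <- suppressWarnings(detect(sim$recording, "ste", n_jobs = 1))
  e4 <- suppressWarnings(detect(sim$recording, "ste", n_jobs = 4))
  expect_equal(as.data.frame(e1), as.data.frame(e4))
  perm <- from_array(sim$recording$signals[c(3, 1, 4, 2), ], FS,
                     sim$recording$channel_names[c(3, 1, 4, 2)])
  ep <- suppressWarnings(detect(perm, "ste"))
  expect_equal(as.data.frame(ep), as.data.frame(e1))
  # single channel equals the channel-level call
  single <- from_array(sim$recording$signals[1, , drop = FALSE], FS, "CH01")
  es <- suppressWarnings(detect(single, "ste"))
  fil <- design_bandpass(filter_spec(80, 500, sample_rate = FS))
  direct <- suppressWarnings(detect_ste_channel(
    apply_zero_phase(sim$recording$signals[1, ], fil), ste_params(), FS))
  expect_equal(es$start, direct$start)
  expect_equal(es$end, direct$end)
  expect_error(detect(sim$recording, "ste", n_jobs = 0), "n_jobs")
  expect_error(detect(sim$recording, "ste", params = mni_params()), "match")
})
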