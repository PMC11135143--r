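test_that("calibration is affine, exact at range endpoints, and matches direct evaluation", {
  cal <- calibration_info(-100, 100, -1000, 1000)
  expect_equal(calibrate(500, cal), 50)            # R = 0.1, O = 0
  withr::with_seed(10, {
    for (k in 1:100) {
      vmin <- runif(1, -500, 0); vmax <- runif(1, 1e-3, 500)
      dmin <- sample(-33000:0, 1); dmax <- dmin + sample(1:66000, 1)
      cc <- calibration_info(vmin, vmax, dmin, dmax)
      expect_equal(calibrate(dmin, cc), vmin, tolerance = 1e-12)
      expect_equal(calibrate(dmax, cc), vmax, tolerance = 1e-12)
      expect_equal(calibrate((dmin + dmax) / 2, cc), (vmin + vmax) / 2,
                   tolerance = 1e-9)
    }
  })
  # symmetric ranges have zero offset
  sym <- calibration_info(-40, 40, -2000, 2000)
  expect_equal(calibrate(rep(0, 5), sym), rep(0, 5))
  expect_error(calibration_info(-1, 1, 5, 5), "d_max")
  expect_error(calibration_info(3, 3, 0, 10), "v_max")
})

test_that("from_array validates shape and names and preserves values", {
  rec <- from_array(matrix(1:8000 / 7, nrow = 2), 2000, c("A1", "A2"))
  expect_equal(duration_s(rec), 2)
  expect_equal(channel_signal(rec, "A2"), (seq(2, 8000, 2)) / 7)
  expect_error(from_array(matrix(0, 2, 10), 2000, "one"), "names")
  expect_error(from_array(matrix(0, 1, 10), 2000, character(0)), "at least one")
  expect_error(from_array(matrix(0, 2, 10), 2000, c("X", "X")), "unique")
  expect_error(from_array(matrix(0, 1, 10), -1, "A"), "sample_rate")
})

test_that("bipolar montage subtracts pairs with the expected names and signs", {
  ramp <- rbind(1:50, (1:50) * 2, (1:50) * 5)
  rec <- from_array(ramp, 1000, c("D1", "D2", "D3"))
  bp <- make_bipolar(rec, list(c("D1", "D2"), c("D2", "D3")))
  expect_equal(bp$channel_names, c("D1-D2", "D2-D3"))
  expect_equal(bp$signals[1, ], -(1:50))
  expect_equal(bp$signals[2, ], (1:50) * -3)
  # antisymmetry and self-difference
  ab <- make_bipolar(rec, list(c("D1", "D3")))
  ba <- make_bipolar(rec, list(c("D3", "D1")))
  expect_equal(ab$signals[1, ], -ba$signals[1, ])
  expect_equal(make_bipolar(rec, list(c("D2", "D2")))$signals[1, ], rep(0, 50))
  expect_error(make_bipolar(rec, list(c("D1", "nope"))), "unknown channel")
})

test_that("EDF round trip reproduces the signal within one quantization step", {
  fs <- 500
  t <- (0:(4 * fs - 1)) / fs
  sig <- rbind(37.5 * sin(2 * pi * 10 * t), 80 * cos(2 * pi * 3 * t))
  rec <- from_array(sig, fs, c("SINE", "COS"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$recording$channel_names, c("SINE", "COS"))
  expect_equal(back$recording$sample_rate, fs)
  for (k in 1:2) {
    step <- (back$calibration$v_max[k] - back$calibration$v_min[k]) /
      (back$calibration$d_max[k] - back$calibration$d_min[k])
    expect_lt(max(abs(back$recording$signals[k, ] - sig[k, ])), step)
  }
  # channel subset comes back in request order
  sub <- read_edf(path, channels = c("COS", "SINE"))
  expect_equal(sub$recording$channel_names, c("COS", "SINE"))
  expect_equal(sub$recording$signals[1, ], back$recording$signals[2, ])
  expect_error(read_edf(path, channels = "missing"), "unknown channel")
  expect_error(read_edf("/no/such/file.edf"), "not found")
})

test_that("an independent EDF reader agrees with ours on a written file", {
  skip_if_not(python_available())
  sim <- simulate_recording(sim_config(duration_s = 3, n_channels = 2,
                                       hfo_count = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".edf")
  ref <- withr::local_tempfile(fileext = ".txt")
  write_edf(sim$recording, path)
  back <- read_edf(path)
  write.table(back$recording$signals, ref, row.names = FALSE, col.names = FALSE)
  out <- system2("python", c("-c", shQuote(sprintf(
    "import mne, numpy as np\nraw = mne.io.read_raw_edf('%s', verbose='error')\nd = raw.get_data()*1e6\nref = np.loadtxt('%s')\nprint(float(np.abs(d - ref).max()))",
    path, ref))), stdout = TRUE, stderr = FALSE)
  expect_lt(as.numeric(out[length(out)]), 1e-6)
})

test_that("event export round trips through both containers", {
  ev <- hfo_events(c("A", "A", "B"), c(10L, 50L, 7L), c(30L, 90L, 22L),
                   detector = "ste", sample_rate = 2000,
                   label = c("artifact", "spkHFO", "non-spkHFO"),
                   prob = c(0.9, 0.8, 0.7),
                   params = list(rms_threshold_sd = 5))
  rds <- withr::local_tempfile(fileext = ".rds")
  export_events(ev, rds, format = "rds")
  expect_identical(read_events(rds), ev)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_events(ev, csv, format = "csv")
  back <- read_events(csv)
  expect_equal(back$channel, ev$channel)
  expect_equal(back$start, ev$start)
  expect_equal(back$end, ev$end)
  expect_equal(back$label, ev$label)
  expect_equal(attr(back, "sample_rate"), 2000)
  expect_equal(attr(back, "params")$rms_threshold_sd, 5)
  # per-channel summary conserves counts
  summ <- read.csv(paste0(csv, ".channels.csv"))
  expect_equal(sum(summ$total), 3)
  expect_equal(summ$total[summ$channel == "A"], 2)
  expect_equal(sum(summ$artifact + summ$spkHFO + summ$non_spkHFO), 3)
})

test_that("empty event sets export to valid files with zero rows", {
  ev <- hfo_events(sample_rate = 1000)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_events(ev, csv, format = "csv")
  back <- read_events(csv)
  expect_equal(nrow(back), 0)
  expect_equal(attr(back, "sample_rate"), 1000)
})
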