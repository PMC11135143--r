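test_that("model construction is deterministic and outputs normalized probabilities", {
  spec <- tiny_model_spec()
  m1 <- build_model(spec, seed = 7)
  m2 <- build_model(spec, seed = 7)
  expect_identical(m1, m2)
  m3 <- build_model(spec, seed = 8)
  expect_false(identical(m1$conv[[1]]$W, m3$conv[[1]]$W))
  p <- predict_proba(m1, array(0, c(32, 32, 1, 3)))
  expect_equal(rowSums(p), rep(1, 3))
  expect_true(all(is.finite(p)))
  expect_error(model_spec(input_channels = 3), "input_channels")
  expect_error(model_spec(input_size = 100, conv_widths = c(8, 8, 8)),
               "divide")
})

test_that("MAC counting reproduces closed-form layer counts and spatial scaling", {
  # single 3x3 conv, 1 -> 8 channels, 128 x 128 same-padded input
  spec1 <- model_spec(1, 128, conv_widths = 8L, head = 1L)
  m <- build_model(spec1, seed = 1)
  conv_macs <- 8 * 128 * 128 * 9
  expect_equal(conv_macs, 1179648)
  dense_macs <- 1 * (64 * 64 * 8) + 2 * 1
  expect_equal(count_macs(m), conv_macs + dense_macs)
})

test_that("conv MACs scale with the square of the input side", {
  spec <- model_spec(1, 128, conv_widths = c(4L, 8L), head = 4L)
  m <- build_model(spec, seed = 1)
  dense <- nrow(m$fc1$W) * ncol(m$fc1$W) + 2 * nrow(m$fc1$W)
  conv_full <- count_macs(m) - dense
  conv_half <- count_macs(m, 64) - dense
  expect_equal(conv_full / conv_half, 4)
  # the default artifact model stays under the pre-pruning budget
  expect_lt(count_macs(build_model(model_spec(1, 128), seed = 1)), 600e6)
})

test_that("training separates separable classes and the checkpoint is the val-loss argmin", {
  d <- tiny_image_set()
  fit <- train_classifier(d$x, d$y, tiny_model_spec(), tiny_train_config())
  expect_gte(max(fit$history$val_acc), 0.9)
  expect_equal(fit$history$val_loss[fit$best_epoch], min(fit$history$val_loss))
  expect_lte(fit$history$val_loss[fit$best_epoch],
             fit$history$val_loss[nrow(fit$history)])
  # reproducibility of the whole seeded run
  fit2 <- train_classifier(d$x, d$y, tiny_model_spec(), tiny_train_config())
  expect_identical(fit$history, fit2$history)
  expect_error(train_classifier(d$x, rep("one", length(d$y))), "class")
})

test_that("cross-validation folds partition the data with 70/10 inner splits", {
  d <- tiny_image_set(25)
  cfg <- tiny_train_config(epochs = 2)
  cv <- cross_validate(d$x, d$y, tiny_model_spec(), cfg)
  n <- length(d$y)
  expect_length(cv$assignments, n)
  expect_equal(sort(unique(cv$assignments)), 1:5)
  expect_equal(sum(table(cv$assignments)), n)       # disjoint + exhaustive
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(c("precision", "recall", "accuracy", "f1") %in%
                    cv$summary$metric))
  expect_true(all(cv$summary$ci_low <= cv$summary$mean &
                    cv$summary$mean <= cv$summary$ci_high))
  cv2 <- cross_validate(d$x, d$y, tiny_model_spec(), cfg)
  expect_identical(cv$assignments, cv2$assignments)
  expect_error(cross_validate(d$x[, , , 1:3, drop = FALSE], d$y[1:3],
                              tiny_model_spec(), cfg), "per fold")
})

test_that("metrics follow the confusion-matrix formulas including undefined cases", {
  y_true <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1)
  y_pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 1, 0)   # TP=3 FP=1 FN=2 TN=4
  m <- compute_metrics(y_true, y_pred, positive = "1")
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  # the spec's hand-worked case: TP=3 FP=1 FN=1 TN=5
  y_t <- c(rep("p", 4), rep("n", 6))
  y_p <- c("p", "p", "p", "n", "p", rep("n", 5))
  m2 <- compute_metrics(y_t, y_p, positive = "p")
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 0.75)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$f1, 0.75)
  perfect <- compute_metrics(c(0, 1, 1), c(0, 1, 1), positive = "1")
  expect_true(all(unlist(perfect) == 1))
  # all-negative prediction with positives present: recall 0, precision NA
  deg <- compute_metrics(c(1, 1, 0), c(0, 0, 0), positive = "1")
  expect_equal(deg$recall, 0)
  expect_true(is.na(deg$precision))
  expect_error(compute_metrics(1:3, 1:4), "length")
  # agrees with an independent tally on random labels
  withr::with_seed(5, {
    for (k in 1:20) {
      yt <- sample(c("a", "b"), 30, replace = TRUE)
      yp <- sample(c("a", "b"), 30, replace = TRUE)
      mm <- compute_metrics(yt, yp, positive = "b")
      tab <- table(factor(yt, c("a", "b")), factor(yp, c("a", "b")))
      expect_equal(mm$accuracy, sum(diag(tab)) / 30)
      if (sum(tab[, "b"]) > 0) {
        expect_equal(mm$precision, tab["b", "b"] / sum(tab[, "b"]))
      }
    }
  })
})

test_that("event prediction applies the edge-second override and conserves labels", {
  sim <- simulate_recording(sim_config(duration_s = 12, n_channels = 1,
                                       hfo_count = 3, seed = 19))
  art <- build_model(model_spec(1, 128), seed = 1); art$levels <- c("artifact", "real")
  spk <- build_model(model_spec(2, 128), seed = 2); spk$levels <- c("non-spkHFO", "spkHFO")
  ev <- sim$truth
  # append events inside the first and last second
  edge <- hfo_events(c("CH01", "CH01"), c(100L, sim$recording$n_samples - 300L),
                     c(400L, sim$recording$n_samples - 100L), sample_rate = FS)
  all_ev <- hfo_events(c(ev$channel, edge$channel), c(ev$start, edge$start),
                       c(ev$end, edge$end), sample_rate = FS)
  pred <- predict_events(sim$recording, all_ev, art, spk)
  expect_equal(nrow(pred), nrow(all_ev))
  expect_true(all(pred$label[4:5] == "artifact"))  # edge rule, any weights
  expect_true(all(pred$label %in% c("artifact", "spkHFO", "non-spkHFO")))
  counts <- table(pred$label)
  expect_equal(sum(counts), nrow(all_ev))
  empty <- predict_events(sim$recording, hfo_events(sample_rate = FS), art, spk)
  expect_equal(nrow(empty), 0)
  expect_error(predict_events(sim$recording, all_ev, spk, art), "1 channel")
})

test_that("pruning strictly reduces MACs, keeps the contract, and retains accuracy", {
  d <- tiny_image_set()
  fit <- train_classifier(d$x, d$y, tiny_model_spec(), tiny_train_config())
  before <- count_macs(fit$model)
  pruned <- prune_model(fit$model, d$x, d$y, iterations = 4,
                        fine_tune_every = 2, fine_tune_epochs = 2,
                        config = tiny_train_config())
  expect_lt(count_macs(pruned), before)
  p <- predict_proba(pruned, d$x)
  expect_equal(dim(p), c(length(d$y), 2))        # output contract unchanged
  acc <- mean(colnames(p)[apply(p, 1, which.max)] == d$y)
  expect_gte(acc, 0.9)
  expect_error(prune_model(fit$model, d$x, d$y, iterations = 2,
                           fine_tune_every = 10, fine_tune_epochs = 1,
                           config = tiny_train_config(), min_width = 64),
               "minimum width")
})

test_that("models round trip through their weights file and sidecar", {
  m <- build_model(tiny_model_spec(), seed = 4)
  m$levels <- c("a", "b")
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back, m)
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(sidecar$spec$input_size, 32)
  expect_equal(sidecar$macs, count_macs(m))
})
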