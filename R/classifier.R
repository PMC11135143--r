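#' Compact convolutional classifier architecture
#'
#' A small stack of 3x3 convolution + ReLU + 2x2 max-pool blocks followed by
#' a two-layer dense head with softmax, sized so that inference is practical
#' on an ordinary CPU. The artifact-rejection model takes the
#' time-frequency image alone (`input_channels = 1`); the spike classifier
#' takes the time-frequency and amplitude-coding images concatenated
#' (`input_channels = 2`). Default widths keep the multiply-accumulate
#' count at 128 x 128 well under 600 M.
#'
#' @param input_channels 1 or 2.
#' @param input_size image side in pixels; must divide by `2^length(conv_widths)`.
#' @param conv_widths output channels of each conv block.
#' @param head hidden width of the dense head.
#' @param kernel convolution kernel side (odd; default 3).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(input_channels = 1L, input_size = 128L,
                       conv_widths = c(8L, 16L, 32L, 32L), head = 32L,
                       kernel = 3L) {
  if (!input_channels %in% c(1L, 2L)) stop("input_channels must be 1 or 2")
  if (input_size %% 2^length(conv_widths) != 0) {
    stop("input_size must divide by 2^(number of conv blocks)")
  }
  if (kernel %% 2 != 1) stop("kernel must be odd")
  structure(list(input_channels = as.integer(input_channels),
                 input_size = as.integer(input_size),
                 conv_widths = as.integer(conv_widths),
                 head = as.integer(head), kernel = as.integer(kernel)),
            class = "model_spec")
}

#' Training protocol settings
#'
#' @param folds cross-validation folds (default 5).
#' @param split train/validation/test fractions of the whole set
#'   (default 0.7/0.1/0.2).
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 128).
#' @param learning_rate Adam learning rate (default 3e-4).
#' @param seed master seed for shuffling, initialization and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(folds = 5L, split = c(0.7, 0.1, 0.2), epochs = 30L,
                         batch_size = 128L, learning_rate = 3e-4, seed = 1L) {
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(folds = as.integer(folds), split = split,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Build a classifier with deterministic initialization
#'
#' He-normal initialization drawn from a generator seeded by `seed`, so the
#' same seed always yields identical parameters.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return object of class `hfo_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  k <- spec$kernel
  with_local_seed(seed, {
    conv <- list()
    cin <- spec$input_channels
    for (cout in spec$conv_widths) {
      fan_in <- k * k * cin
      conv[[length(conv) + 1]] <- list(
        W = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                   nrow = cout),
        b = rep(0, cout))
      cin <- cout
    }
    s_out <- spec$input_size / 2^length(spec$conv_widths)
    flat <- s_out^2 * cin
    model <- structure(list(
      spec = spec,
      conv = conv,
      fc1 = list(W = matrix(stats::rnorm(spec$head * flat, sd = sqrt(2 / flat)),
                            nrow = spec$head), b = rep(0, spec$head)),
      fc2 = list(W = matrix(stats::rnorm(2 * spec$head, sd = sqrt(2 / spec$head)),
                            nrow = 2), b = rep(0, 2)),
      levels = NULL), class = "hfo_model")
    model
  })
}

#' @export
print.hfo_model <- function(x, ...) {
  widths <- vapply(x$conv, function(l) nrow(l$W), 0L)
  cat(sprintf("<hfo_model> %dx%dx%d input, conv widths [%s], head %d, %.1f M MACs\n",
              x$spec$input_size, x$spec$input_size, x$spec$input_channels,
              paste(widths, collapse = ", "), nrow(x$fc1$W),
              count_macs(x) / 1e6))
  invisible(x)
}

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4L) stop("expected an (H, W, C, N) image array")
  x
}

model_forward <- function(model, x, keep_cache = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  if (d[1] != model$spec$input_size || d[3] != model$spec$input_channels) {
    stop("geometry mismatch between features and model")
  }
  k <- model$spec$kernel
  cache <- list(conv = list())
  a <- x
  for (l in seq_along(model$conv)) {
    din <- dim(a)
    z <- conv2d_fw(a, as.integer(din), model$conv[[l]]$W, model$conv[[l]]$b, k)
    r <- pmax(z, 0); dim(r) <- dim(z)
    p <- maxpool2_fw(r, as.integer(dim(r)))
    if (keep_cache) {
      cache$conv[[l]] <- list(input = a, in_dims = as.integer(din),
                              mask = z > 0, pool_idx = p$idx,
                              r_dims = as.integer(dim(r)))
    }
    a <- p$y
  }
  dp <- dim(a)
  flat <- a; dim(flat) <- c(prod(dp[1:3]), dp[4])
  h_pre <- model$fc1$W %*% flat + model$fc1$b
  h <- pmax(h_pre, 0)
  logits <- model$fc2$W %*% h + model$fc2$b
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), "/")
  out <- list(probs = probs)
  if (keep_cache) {
    out$cache <- c(cache, list(flat = flat, flat_dims = dp,
                               h_pre = h_pre, h = h))
  }
  out
}

model_grads <- function(model, x, y_idx) {
  x <- as_batch(x)
  n <- dim(x)[4]
  fw <- model_forward(model, x, keep_cache = TRUE)
  p <- fw$probs
  loss <- -mean(log(pmax(p[cbind(y_idx, seq_len(n))], 1e-12)))
  dlogit <- p
  dlogit[cbind(y_idx, seq_len(n))] <- dlogit[cbind(y_idx, seq_len(n))] - 1
  dlogit <- dlogit / n
  cache <- fw$cache
  g <- list(conv = vector("list", length(model$conv)))
  g$fc2 <- list(W = dlogit %*% t(cache$h), b = rowSums(dlogit))
  dh <- (t(model$fc2$W) %*% dlogit) * (cache$h_pre > 0)
  g$fc1 <- list(W = dh %*% t(cache$flat), b = rowSums(dh))
  dflat <- t(model$fc1$W) %*% dh
  da <- dflat; dim(da) <- cache$flat_dims
  k <- model$spec$kernel
  for (l in rev(seq_along(model$conv))) {
    cc <- cache$conv[[l]]
    dr <- maxpool2_bw(da, cc$pool_idx, cc$r_dims)
    dz <- dr * cc$mask
    bw <- conv2d_bw(cc$input, cc$in_dims, model$conv[[l]]$W, k, dz)
    g$conv[[l]] <- list(W = bw$dW, b = as.numeric(bw$db))
    da <- bw$dx
  }
  list(loss = loss, grads = g)
}

# flat parameter walk shared by the Adam update
param_paths <- function(model) {
  c(lapply(seq_along(model$conv), function(l) c("conv", l, "W")),
    lapply(seq_along(model$conv), function(l) c("conv", l, "b")),
    list(c("fc1", "W"), c("fc1", "b"), c("fc2", "W"), c("fc2", "b")))
}

get_path <- function(obj, path) {
  for (p in path) obj <- obj[[if (grepl("^[0-9]+$", p)) as.integer(p) else p]]
  obj
}

set_path <- function(obj, path, value) {
  if (length(path) == 1L) {
    obj[[if (grepl("^[0-9]+$", path)) as.integer(path) else path]] <- value
    return(obj)
  }
  key <- if (grepl("^[0-9]+$", path[1])) as.integer(path[1]) else path[1]
  obj[[key]] <- set_path(obj[[key]], path[-1], value)
  obj
}

adam_update <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(state$paths)) {
    path <- state$paths[[i]]
    gr <- get_path(grads, path)
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * gr
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * gr^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    val <- get_path(model, path) - lr * mhat / (sqrt(vhat) + eps)
    model <- set_path(model, path, val)
  }
  list(model = model, state = state)
}

adam_init <- function(model) {
  paths <- lapply(param_paths(model), as.character)
  list(t = 0, paths = paths,
       m = lapply(paths, function(p) get_path(model, p) * 0),
       v = lapply(paths, function(p) get_path(model, p) * 0))
}

eval_loss_acc <- function(model, x, y_idx, batch = 256L) {
  x <- as_batch(x)
  n <- dim(x)[4]
  loss <- 0; correct <- 0
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    p <- model_forward(model, x[, , , s:e, drop = FALSE])$probs
    yi <- y_idx[s:e]
    loss <- loss + sum(-log(pmax(p[cbind(yi, seq_along(yi))], 1e-12)))
    correct <- correct + sum(apply(p, 2, which.max) == yi)
  }
  list(loss = loss / n, acc = correct / n)
}

# core training loop: Adam minibatches with optional per-sample
# augmentation on the training stream only; returns the checkpoint with the
# minimum validation loss
train_loop <- function(model, x_tr, y_tr, x_val, y_val, config,
                       augment_fn = NULL) {
  x_tr <- as_batch(x_tr); x_val <- as_batch(x_val)
  n <- dim(x_tr)[4]
  state <- adam_init(model)
  best <- list(val_loss = Inf, model = model, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- x_tr[, , , idx, drop = FALSE]
      if (!is.null(augment_fn)) {
        for (j in seq_along(idx)) xb[, , , j] <- augment_fn(idx[j])
      }
      res <- model_grads(model, xb, y_tr[idx])
      up <- adam_update(model, res$grads, state, config$learning_rate)
      model <- up$model; state <- up$state
      ep_loss <- ep_loss + res$loss; nb <- nb + 1
    }
    ev <- eval_loss_acc(model, x_val, y_val)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (ev$loss < best$val_loss) {
      best <- list(val_loss = ev$loss, model = model, epoch = ep)
    }
  }
  list(model = best$model, best_epoch = best$epoch, history = hist,
       final_model = model)
}

label_index <- function(y, levels = NULL) {
  y <- as.character(y)
  if (is.null(levels)) levels <- sort(unique(y))
  if (length(levels) != 2L) stop("exactly two classes are required")
  idx <- match(y, levels)
  if (anyNA(idx)) stop("labels outside the model's classes")
  list(idx = idx, levels = levels)
}

#' Train a classifier with the standard protocol
#'
#' Shuffles the data (seeded), splits it into train/validation/test by the
#' config fractions, and runs Adam minibatch training for the configured
#' epochs, applying `augment_fn` (if given) to every training sample in
#' every epoch — the validation and test splits are never augmented. The
#' returned model is the epoch checkpoint with minimum validation loss.
#'
#' @param x image array `(H, W, C, N)`.
#' @param y two-class labels, length N.
#' @param spec a [model_spec()] (default sized from `x`).
#' @param config a [train_config()].
#' @param augment_fn optional `function(i)` returning a (possibly
#'   augmented) `(H, W, C)` image for sample `i`; draws from the current
#'   RNG stream.
#' @return list with `model` (checkpoint, carrying the class levels),
#'   `history` (per-epoch train/val loss and val accuracy), `best_epoch`,
#'   `split` (index vectors), and `test` metrics of the checkpoint.
#' @export
train_classifier <- function(x, y, spec = NULL, config = train_config(),
                             augment_fn = NULL) {
  x <- as_batch(x)
  d <- dim(x)
  lab <- label_index(y)
  if (length(unique(lab$idx)) < 2L) stop("training data has a single class")
  if (is.null(spec)) {
    spec <- model_spec(input_channels = d[3], input_size = d[1])
  }
  with_local_seed(config$seed, {
    n <- d[4]
    ord <- sample.int(n)
    n_tr <- round(config$split[1] * n)
    n_val <- round(config$split[2] * n)
    if (n_tr < 1 || n_val < 1 || n_tr + n_val >= n) stop("split leaves an empty subset")
    i_tr <- ord[seq_len(n_tr)]
    i_val <- ord[n_tr + seq_len(n_val)]
    i_te <- ord[(n_tr + n_val + 1L):n]
    model <- build_model(spec, seed = config$seed)
    aug <- if (is.null(augment_fn)) NULL else function(j) augment_fn(i_tr[j])
    fit <- train_loop(model, x[, , , i_tr, drop = FALSE], lab$idx[i_tr],
                      x[, , , i_val, drop = FALSE], lab$idx[i_val],
                      config, aug)
    fit$model$levels <- lab$levels
    te <- eval_loss_acc(fit$model, x[, , , i_te, drop = FALSE], lab$idx[i_te])
    list(model = fit$model, history = fit$history, best_epoch = fit$best_epoch,
         split = list(train = i_tr, val = i_val, test = i_te),
         test = te)
  })
}

#' Class probabilities for a batch of images
#'
#' @param model an `hfo_model` with class levels.
#' @param x image array `(H, W, C, N)` or a single `(H, W, C)` image.
#' @param batch inference batch size (default 256; inference is batched on
#'   CPU).
#' @return N x 2 matrix of probabilities, columns named by class level.
#' @export
predict_proba <- function(model, x, batch = 256L) {
  x <- as_batch(x)
  n <- dim(x)[4]
  out <- matrix(0, n, 2)
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    out[s:e, ] <- t(model_forward(model, x[, , , s:e, drop = FALSE])$probs)
  }
  if (!is.null(model$levels)) colnames(out) <- model$levels
  out
}

#' Five-fold cross-validation with the standard protocol
#'
#' Shuffles the data once (seeded) and divides it into `config$folds`
#' groups; each group is the test set of one fold, and the remaining data
#' splits into training and validation so they are 70% and 10% of the whole
#' set. Reports per-fold metrics and their mean with a normal-theory 95%
#' confidence interval.
#'
#' @inheritParams train_classifier
#' @return list with `folds` (per-fold metric data frame), `summary` (mean,
#'   ci_low, ci_high per metric), and `assignments` (test-fold id per
#'   sample).
#' @export
cross_validate <- function(x, y, spec = NULL, config = train_config(),
                           augment_fn = NULL) {
  x <- as_batch(x)
  n <- dim(x)[4]
  if (n < config$folds) stop("need at least one sample per fold")
  lab <- label_index(y)
  if (is.null(spec)) {
    spec <- model_spec(input_channels = dim(x)[3], input_size = dim(x)[1])
  }
  fold_of <- with_local_seed(config$seed,
    sample(rep_len(seq_len(config$folds), n)))
  rows <- list()
  for (f in seq_len(config$folds)) {
    i_te <- which(fold_of == f)
    rest <- which(fold_of != f)
    res <- with_local_seed(config$seed + f, {
      rest <- sample(rest)
      # 70 / 10 of the WHOLE dataset, carved out of the remaining 80%
      n_tr <- round(0.7 * n)
      i_tr <- rest[seq_len(min(n_tr, length(rest) - 1L))]
      i_val <- rest[(length(i_tr) + 1L):length(rest)]
      model <- build_model(spec, seed = config$seed + f)
      aug <- if (is.null(augment_fn)) NULL else function(j) augment_fn(i_tr[j])
      fit <- train_loop(model, x[, , , i_tr, drop = FALSE], lab$idx[i_tr],
                        x[, , , i_val, drop = FALSE], lab$idx[i_val],
                        config, aug)
      fit$model$levels <- lab$levels
      pr <- predict_proba(fit$model, x[, , , i_te, drop = FALSE])
      y_pred <- lab$levels[apply(pr, 1, which.max)]
      compute_metrics(lab$levels[lab$idx[i_te]], y_pred,
                      positive = lab$levels[2])
    })
    rows[[f]] <- data.frame(fold = f, precision = res$precision,
                            recall = res$recall, accuracy = res$accuracy,
                            f1 = res$f1)
  }
  folds <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(c("precision", "recall", "accuracy", "f1"),
    function(mn) {
      v <- folds[[mn]]
      mu <- mean(v); half <- 1.96 * stats::sd(v) / sqrt(length(v))
      data.frame(metric = mn, mean = mu, ci_low = mu - half, ci_high = mu + half)
    }))
  list(folds = folds, summary = summ, assignments = fold_of)
}

#' Binary classification metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` and F1 (the harmonic mean of precision and
#' recall). A zero denominator yields `NA` (undefined, deliberately
#' distinct from 0).
#'
#' @param y_true,y_pred equal-length binary label vectors.
#' @param positive the positive-class label (defaults to the second sorted
#'   level).
#' @return list `precision`, `recall`, `accuracy`, `f1`.
#' @examples
#' compute_metrics(c(1,1,1,1,0,0,0,0,0,1), c(1,1,1,0,0,0,0,0,1,0))
#' @export
compute_metrics <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(positive)) positive <- sort(unique(c(y_true, y_pred)))[2]
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  prec <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec,
       accuracy = div(tp + tn, tp + tn + fp + fn), f1 = f1)
}

#' Count multiply-accumulate operations
#'
#' Analytic layer formulas: each convolution contributes
#' `H_out * W_out * kernel^2 * C_in * C_out` MACs, each dense layer its
#' weight-matrix product size. Deterministic in the model's current widths,
#' so pruning is directly measurable.
#'
#' @param model an `hfo_model`.
#' @param input_size optional input side override (spatial dims scale as
#'   its square).
#' @return integer-valued numeric MAC count.
#' @export
count_macs <- function(model, input_size = NULL) {
  if (is.null(input_size)) input_size <- model$spec$input_size
  k <- model$spec$kernel
  macs <- 0
  s <- input_size
  for (l in seq_along(model$conv)) {
    cout <- nrow(model$conv[[l]]$W)
    cin <- ncol(model$conv[[l]]$W) / (k * k)
    macs <- macs + s * s * k * k * cin * cout
    s <- s / 2
  }
  macs + nrow(model$fc1$W) * ncol(model$fc1$W) +
    nrow(model$fc2$W) * ncol(model$fc2$W)
}

#' Classify detected events with the artifact and spike models
#'
#' For each event, the event-centered window is extracted (no
#' augmentation), the artifact model scores its time-frequency image, and
#' events it accepts as real HFOs are scored by the spike model on the
#' concatenated time-frequency + amplitude-coding input. Events whose
#' window touches the first or last second of the recording are labelled
#' `artifact` regardless of the model output (recording edges produce
#' filter and montage artifacts). Inference runs in fixed-size batches on
#' the CPU.
#'
#' @param rec an `hfo_recording`.
#' @param events an `hfo_events` set.
#' @param artifact_model 1-channel `hfo_model` whose levels include
#'   `"artifact"`.
#' @param spk_model 2-channel `hfo_model` whose levels include `"spkHFO"`.
#' @param geometry an [image_geometry()] matching the models' input size.
#' @return the event set with `label` and `prob` filled in (`prob` is the
#'   probability of the assigned label).
#' @export
predict_events <- function(rec, events, artifact_model, spk_model,
                           geometry = image_geometry()) {
  if (artifact_model$spec$input_channels != 1L ||
      spk_model$spec$input_channels != 2L) {
    stop("artifact model must take 1 channel and spk model 2")
  }
  n <- nrow(events)
  if (n == 0L) return(events)
  size <- geometry$size
  if (size != artifact_model$spec$input_size) stop("geometry mismatch")
  x <- array(0, c(size, size, 2L, n))
  for (i in seq_len(n)) {
    win <- extract_window(rec, events[i, ], half_width_ms = geometry$half_width_ms)
    x[, , 1, i] <- time_frequency_image(win, rec$sample_rate, geometry)$grid
    x[, , 2, i] <- amplitude_coding_image(win, geometry)$grid
  }
  pa <- predict_proba(artifact_model, x[, , 1, , drop = FALSE])
  p_art <- pa[, "artifact"]
  is_art <- p_art >= 0.5
  lab <- rep(NA_character_, n); prob <- rep(NA_real_, n)
  lab[is_art] <- "artifact"; prob[is_art] <- p_art[is_art]
  real <- which(!is_art)
  if (length(real)) {
    ps <- predict_proba(spk_model, x[, , , real, drop = FALSE])
    p_spk <- ps[, "spkHFO"]
    lab[real] <- ifelse(p_spk >= 0.5, "spkHFO", "non-spkHFO")
    prob[real] <- pmax(p_spk, 1 - p_spk)
  }
  # rule-based edge filter: first/last second of the recording
  fs <- rec$sample_rate
  edge <- events$start < fs | events$end > rec$n_samples - fs
  lab[edge] <- "artifact"
  events$label <- lab
  events$prob <- prob
  events
}

#' Structured channel pruning with dependency propagation
#'
#' Iteratively removes the convolution output channel with the smallest
#' aggregate weight magnitude, propagating the removal to the dependent
#' input slice of the next layer (or the dense head for the last block),
#' and fine-tunes periodically. The returned model keeps the input/output
#' contract and has strictly fewer MACs. Defaults mirror the full protocol
#' (5000 iterations, fine-tune every 250 by 5 epochs); tests use a reduced
#' preset.
#'
#' @param model a trained `hfo_model`.
#' @param x,y fine-tuning data (images and labels).
#' @param iterations channel-removal iterations.
#' @param fine_tune_every fine-tune cadence in iterations.
#' @param fine_tune_epochs epochs per fine-tune.
#' @param config a [train_config()] supplying optimizer settings.
#' @param min_width smallest width any layer may reach.
#' @return the pruned (and fine-tuned) `hfo_model`.
#' @export
prune_model <- function(model, x, y, iterations = 5000L,
                        fine_tune_every = 250L, fine_tune_epochs = 5L,
                        config = train_config(), min_width = 2L) {
  x <- as_batch(x)
  lab <- label_index(y, model$levels)
  k <- model$spec$kernel
  ft_cfg <- config; ft_cfg$epochs <- as.integer(fine_tune_epochs)
  fine_tune <- function(m) {
    n <- dim(x)[4]
    i_val <- seq_len(max(2L, round(0.2 * n)))
    i_tr <- setdiff(seq_len(n), i_val)
    fit <- train_loop(m, x[, , , i_tr, drop = FALSE], lab$idx[i_tr],
                      x[, , , i_val, drop = FALSE], lab$idx[i_val], ft_cfg)
    fit$final_model
  }
  removed <- 0L
  for (it in seq_len(iterations)) {
    # channel importance: L2 norm of each conv filter
    best <- NULL
    for (l in seq_along(model$conv)) {
      Wl <- model$conv[[l]]$W
      if (nrow(Wl) <= min_width) next
      norms <- sqrt(rowSums(Wl^2))
      j <- which.min(norms)
      if (is.null(best) || norms[j] < best$norm) {
        best <- list(layer = l, channel = j, norm = norms[j])
      }
    }
    if (is.null(best)) break      # every layer at minimum width
    l <- best$layer; j <- best$channel
    model$conv[[l]]$W <- model$conv[[l]]$W[-j, , drop = FALSE]
    model$conv[[l]]$b <- model$conv[[l]]$b[-j]
    if (l < length(model$conv)) {
      # drop the dependent k*k input-slice columns of the next conv
      drop_cols <- (j - 1L) * k * k + seq_len(k * k)
      model$conv[[l + 1]]$W <- model$conv[[l + 1]]$W[, -drop_cols, drop = FALSE]
    } else {
      s_out <- model$spec$input_size / 2^length(model$conv)
      drop_cols <- (j - 1L) * s_out^2 + seq_len(s_out^2)
      model$fc1$W <- model$fc1$W[, -drop_cols, drop = FALSE]
    }
    removed <- removed + 1L
    if (removed %% fine_tune_every == 0L) model <- fine_tune(model)
  }
  if (removed == 0L) stop("pruning target below minimum width: nothing removable")
  fine_tune(model)
}

#' Save / load a classifier
#'
#' The weights go to an RDS file and a JSON sidecar (`<path>.json`) records
#' the architecture and class levels, so a reloaded model is verifiable
#' against its expected geometry.
#'
#' @param model an `hfo_model`.
#' @param path weights file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(spec = unclass(model$spec), levels = model$levels,
                  macs = count_macs(model))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "hfo_model")) stop("not a saved classifier")
  model
}
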