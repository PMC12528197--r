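# Training harness: Adam on the combined loss (cross-entropy + adaptive-mask
# retention penalty + mask magnitude regularizer), stratified epoch-level
# splits, early stopping on validation loss, noise-robustness sweeps and the
# hyperparameter ablation grid.

#' Training specification
#'
#' @param lr Adam learning rate (default 0.001; the explored grid spans
#'   0.0001-0.005).
#' @param batch_size minibatch size in epochs (default 32).
#' @param max_epochs maximal training passes over the data (default 100).
#' @param patience early-stopping patience on validation loss (default 10).
#' @param split named fractions for train/val/test; must sum to 1. Splits
#'   are epoch-level and stratified by class.
#' @param seed integer seed driving the split, shuffling and dropout.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(lr = 0.001, batch_size = 32L, max_epochs = 100L,
                       patience = 10L,
                       split = c(train = 0.6, val = 0.2, test = 0.2),
                       seed = 1L) {
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), split = split,
                 seed = as.integer(seed)),
            class = "train_spec")
}

#' Stratified epoch-level split
#'
#' @param labels factor of per-epoch class labels.
#' @param split named train/val/test fractions summing to 1.
#' @param seed integer seed.
#' @return list of disjoint integer index vectors `train`, `val`, `test`
#'   covering all epochs; each class is represented proportionally.
#' @export
stratified_split <- function(labels, split = c(train = 0.6, val = 0.2,
                                               test = 0.2), seed = 1L) {
  labels <- factor(labels)
  with_local_seed(seed, {
    out <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      n_tr <- round(split[["train"]] * n)
      n_va <- round(split[["val"]] * n)
      out$train <- c(out$train, idx[seq_len(n_tr)])
      out$val <- c(out$val, idx[n_tr + seq_len(min(n_va, n - n_tr))])
      if (n > n_tr + n_va) out$test <- c(out$test, idx[(n_tr + n_va + 1L):n])
    }
    lapply(out, sort)
  })
}

model_frames <- function(config, epochs) {
  frame_epochs(epochs, config$seq_len, config$layout)$frames
}

#' Default model configuration for an epoch set
#'
#' Convenience builder deriving `n_channels`, `frame_dim` and `n_classes`
#' from the data.
#'
#' @param epochs a labelled [eeg_epochs()].
#' @param seq_len frames per epoch.
#' @param ... further arguments passed to [model_config()].
#' @return A [model_config()].
#' @export
config_for <- function(epochs, seq_len = 16L, ...) {
  stopifnot(inherits(epochs, "eeg_epochs"), !is.null(epochs$labels))
  d <- dim(epochs$epochs)
  dots <- list(...)
  layout <- if (!is.null(dots$layout)) dots$layout else "raw_frames"
  fd <- if (layout == "band_frames") 5L else d[3L] %/% seq_len
  do.call(model_config, c(list(n_classes = nlevels(epochs$labels),
                               n_channels = d[2L], seq_len = seq_len,
                               frame_dim = fd), dots))
}

#' Train the adaptive-attention transformer
#'
#' Minimizes `cross-entropy + mask_lambda * mask_loss +
#' mask_sparsity_lambda * mean(M)` with Adam. Runs are deterministic given
#' `spec$seed` (split, shuffling, dropout and initialisation all derive
#' from it). Training history logs every loss component per step; early
#' stopping restores the best-validation-loss weights.
#'
#' @param epochs a labelled [eeg_epochs()] with at least two classes and at
#'   least 10 epochs per class.
#' @param config a [model_config()] (default: [config_for()] on the data).
#' @param spec a [train_spec()].
#' @param verbose print per-epoch progress.
#' @return A trained `eeg_transformer` with fields `classes`, `history`
#'   (per-step data.frame), `val_history`, `split` (index lists), `spec`.
#' @export
train_model <- function(epochs, config = NULL, spec = train_spec(),
                        verbose = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(epochs$labels)) stop("epochs must be labelled", call. = FALSE)
  labels <- factor(epochs$labels)
  if (nlevels(labels) < 2L)
    stop("training needs at least two classes", call. = FALSE)
  if (min(table(labels)) < 10L)
    stop("training needs at least 10 epochs per class", call. = FALSE)
  if (is.null(config)) config <- config_for(epochs)
  config$seed <- spec$seed
  frames <- model_frames(config, epochs)
  y <- as.integer(labels)
  sp <- stratified_split(labels, spec$split, spec$seed)
  model <- init_model(config)
  model$classes <- levels(labels)

  theta <- flatten_params(model$params)
  m_adam <- numeric(length(theta)); v_adam <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  hist <- list(); vhist <- list()
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  step <- 0L
  val_frames <- frames[sp$val, , , , drop = FALSE]
  val_y <- y[sp$val]

  with_local_seed(spec$seed, {
    for (ep in seq_len(spec$max_epochs)) {
      order_idx <- sample(sp$train)
      batches <- split(order_idx,
                       ceiling(seq_along(order_idx) / spec$batch_size))
      for (bt in batches) {
        step <- step + 1L
        model$params <- unflatten_params(model$params, theta)$value
        fw <- transformer_forward(model,
                                  frames[bt, , , , drop = FALSE],
                                  labels = y[bt], training = TRUE,
                                  keep_cache = TRUE)
        if (!is.finite(fw$loss))
          stop("training diverged at step ", step,
               " (loss = ", fw$loss, "); lower the learning rate",
               call. = FALSE)
        gr <- flatten_params(transformer_backward(model, fw$cache))
        m_adam <- beta1 * m_adam + (1 - beta1) * gr
        v_adam <- beta2 * v_adam + (1 - beta2) * gr^2
        mh <- m_adam / (1 - beta1^step)
        vh <- v_adam / (1 - beta2^step)
        theta <- theta - spec$lr * mh / (sqrt(vh) + eps)
        hist[[step]] <- data.frame(step = step, epoch = ep, loss = fw$loss,
                                    ce = fw$ce, mask_loss = fw$mask_loss,
                                    sparsity = fw$sparsity)
      }
      model$params <- unflatten_params(model$params, theta)$value
      vl <- transformer_forward(model, val_frames, labels = val_y)
      vacc <- mean(vl$pred == val_y)
      vhist[[ep]] <- data.frame(epoch = ep, val_loss = vl$loss,
                                 val_accuracy = vacc)
      if (verbose)
        message(sprintf("epoch %3d  val_loss %.4f  val_acc %.3f",
                        ep, vl$loss, vacc))
      if (vl$loss < best$loss - 1e-6)
        best <- list(loss = vl$loss, theta = theta, epoch = ep)
      else if (ep - best$epoch >= spec$patience) break
    }
  })
  model$params <- unflatten_params(model$params, best$theta)$value
  model$history <- do.call(rbind, hist)
  model$val_history <- do.call(rbind, vhist)
  model$split <- sp
  model$spec <- spec
  model
}

#' Predict class probabilities for epochs
#'
#' @param model a trained `eeg_transformer`.
#' @param epochs an [eeg_epochs()] shaped like the training data.
#' @param batch_size forward batch size.
#' @param collect_attention also return attention maps (single batch only).
#' @return list with `probs` (B x K, columns named by class), `pred`
#'   (factor), optionally `attention`, `mask_loss`.
#' @export
predict_model <- function(model, epochs, batch_size = 64L,
                          collect_attention = FALSE) {
  stopifnot(inherits(model, "eeg_transformer"))
  frames <- model_frames(model$config, epochs)
  B <- dim(frames)[1L]
  probs <- matrix(0, B, model$config$n_classes,
                  dimnames = list(NULL, model$classes))
  attention <- NULL; mask_loss <- numeric(0)
  for (i0 in seq.int(1L, B, by = batch_size)) {
    ii <- i0:min(i0 + batch_size - 1L, B)
    fw <- transformer_forward(model, frames[ii, , , , drop = FALSE],
                              collect_attention = collect_attention)
    probs[ii, ] <- fw$probs
    mask_loss <- c(mask_loss, fw$mask_loss)
    if (collect_attention && is.null(attention)) attention <- fw$attention
  }
  list(probs = probs,
       pred = factor(model$classes[max.col(probs, ties.method = "first")],
                     levels = model$classes),
       attention = attention, mask_loss = mean(mask_loss))
}

#' Evaluate a trained model on held-out epochs
#'
#' @param model a trained `eeg_transformer`.
#' @param epochs a labelled [eeg_epochs()] disjoint from the training split.
#' @param positive positive class for binary metrics.
#' @return A [metrics_report()].
#' @export
evaluate_model <- function(model, epochs, positive = NULL) {
  if (is.null(epochs$labels))
    stop("evaluation data must be labelled", call. = FALSE)
  truth <- factor(epochs$labels, levels = model$classes)
  if (anyNA(truth))
    stop("evaluation labels outside the model's class set", call. = FALSE)
  pr <- predict_model(model, epochs)
  metrics_report(truth, pr$pred, pr$probs, positive = positive)
}

#' Noise-robustness sweep
#'
#' Re-evaluates a trained model after injecting calibrated Gaussian noise
#' at each level (percent of per-trace SD, via [add_gaussian_noise()]).
#' Level 0 reproduces the clean evaluation exactly.
#'
#' @param model a trained `eeg_transformer`.
#' @param clean_epochs labelled clean evaluation epochs.
#' @param levels numeric vector of noise percentages (non-empty, >= 0).
#' @param seed integer seed for the noise draws.
#' @return A data.frame with one row per level (level + the six metrics);
#'   full [metrics_report()]s in attribute `"reports"`.
#' @export
noise_robustness <- function(model, clean_epochs, levels = c(0, 10, 20, 30),
                             seed = 1L) {
  if (length(levels) == 0L) stop("empty noise level list", call. = FALSE)
  if (any(levels < 0)) stop("noise levels must be >= 0", call. = FALSE)
  reports <- list()
  rows <- list()
  for (k in seq_along(levels)) {
    lv <- levels[k]
    noisy <- add_gaussian_noise(clean_epochs, lv,
                                seed = seed + 1000L * k)
    rep_k <- evaluate_model(model, noisy)
    reports[[as.character(lv)]] <- rep_k
    rows[[k]] <- cbind(data.frame(level = lv), as.data.frame(rep_k))
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}

#' Hyperparameter ablation grid
#'
#' Trains and evaluates one model per (heads, depth, learning-rate) cell
#' with a shared seed. `d_model` is rounded up to the nearest multiple of
#' the head count so every cell is well-formed.
#'
#' @param epochs labelled [eeg_epochs()].
#' @param heads head counts (default c(4, 8, 12)).
#' @param depths encoder depths (default c(3, 6)).
#' @param lrs learning rates (default 0.001).
#' @param config base [model_config()] (default [config_for()]).
#' @param spec base [train_spec()].
#' @param csv_path optional path to write the results table as CSV.
#' @return data.frame with one row per cell: heads, depth, lr, d_model and
#'   the six test metrics.
#' @export
ablation_grid <- function(epochs, heads = c(4L, 8L, 12L), depths = c(3L, 6L),
                          lrs = 0.001, config = NULL, spec = train_spec(),
                          csv_path = NULL) {
  if (length(heads) == 0L || length(depths) == 0L || length(lrs) == 0L)
    stop("empty ablation grid", call. = FALSE)
  if (is.null(config)) config <- config_for(epochs)
  rows <- list(); k <- 0L
  for (h in heads) for (dp in depths) for (lr in lrs) {
    cfg <- config
    cfg$n_heads <- as.integer(h)
    cfg$n_layers <- as.integer(dp)
    d_new <- as.integer(ceiling(cfg$d_model / h) * h)
    if (d_new != cfg$d_model) {
      cfg$d_ff <- as.integer(round(cfg$d_ff * d_new / cfg$d_model))
      cfg$d_model <- d_new
    }
    sp <- spec; sp$lr <- lr
    fit <- train_model(epochs, cfg, sp)
    rep_cell <- evaluate_model(fit, epochs[fit$split$test])
    k <- k + 1L
    rows[[k]] <- cbind(data.frame(heads = h, depth = dp, lr = lr,
                                  d_model = cfg$d_model),
                       as.data.frame(rep_cell))
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  out
}
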