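# Training harness: metric identities, AUC limits, splits, optimisation
# behaviour, determinism, noise sweeps and the ablation grid.

test_that("metrics match hand arithmetic on a fixed confusion table", {
  m <- metrics_from_counts(tp = 50, fp = 10, fn = 5, tn = 35)
  expect_equal(m$accuracy, 85 / 100)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$specificity, 35 / 45)
  expect_equal(m$f1, 2 * (50 / 60) * (50 / 55) / (50 / 60 + 50 / 55))
})

test_that("metric identities hold on random confusion tables", {
  set.seed(100)
  for (i in 1:1000) {
    ct <- rmultinom(1, sample(20:200, 1), rep(0.25, 4))
    m <- metrics_from_counts(ct[1], ct[2], ct[3], ct[4])
    expect_equal(m$accuracy, (ct[1] + ct[4]) / sum(ct))
    if (!is.na(m$f1))
      expect_equal(m$f1,
                   2 * m$precision * m$recall / (m$precision + m$recall))
  }
})

test_that("AUC attains its analytic limits and flags degenerate scores", {
  truth <- factor(rep(c("a", "b"), each = 20), levels = c("a", "b"))
  scores <- cbind(a = 1 - as.numeric(truth == "b"),
                  b = as.numeric(truth == "b"))
  r <- metrics_report(truth, truth, scores)
  expect_equal(r$auc, 1)
  anti <- cbind(a = scores[, "b"], b = scores[, "a"])
  r2 <- metrics_report(truth, truth, anti)
  expect_equal(r2$auc, 0)
  # constant scores are flagged undefined, not silently scored
  const <- cbind(a = rep(0.5, 40), b = rep(0.5, 40))
  r3 <- metrics_report(truth, truth, const)
  expect_true(is.na(r3$auc))
  expect_match(paste(r3$undefined, collapse = " "), "degenerate")
})

test_that("constant single-class prediction on balanced data scores chance", {
  truth <- factor(rep(c("a", "b"), each = 25), levels = c("a", "b"))
  pred <- factor(rep("a", 50), levels = c("a", "b"))
  r <- metrics_report(truth, pred, positive = "a")
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$recall, 1)      # positive class fully recalled
  expect_equal(r$specificity, 0)
})

test_that("perfect predictions score 1 everywhere", {
  truth <- factor(rep(c("a", "b"), 10))
  scores <- cbind(a = as.numeric(truth == "a"), b = as.numeric(truth == "b"))
  r <- metrics_report(truth, truth, scores)
  for (f in c("accuracy", "precision", "recall", "specificity", "f1", "auc"))
    expect_equal(r[[f]], 1)
})

test_that("stratified splits are disjoint, covering and reproducible", {
  labels <- factor(rep(c("a", "b"), c(60, 40)))
  s1 <- stratified_split(labels, seed = 5)
  s2 <- stratified_split(labels, seed = 5)
  expect_identical(s1, s2)
  all_idx <- sort(c(s1$train, s1$val, s1$test))
  expect_identical(all_idx, seq_along(labels))
  expect_length(intersect(s1$train, s1$test), 0)
  expect_length(intersect(s1$train, s1$val), 0)
  # stratification: class proportions preserved in the training split
  expect_equal(mean(labels[s1$train] == "a"), 0.6, tolerance = 0.05)
})

test_that("training reduces the loss on a separable task", {
  task <- mini_task(epochs_per_class = 20L, n_channels = 2L)
  cfg <- config_for(task, n_layers = 1L, n_heads = 2L, d_model = 16L,
                    d_ff = 32L, dropout = 0)
  fit <- train_model(task, cfg, train_spec(batch_size = 8L, max_epochs = 12L,
                                           patience = 12L, seed = 2L))
  h <- fit$history$loss
  k <- min(10L, floor(length(h) / 2))
  expect_lt(mean(utils::tail(h, k)), mean(utils::head(h, k)))
  # mask loss stays within its row-count bound throughout
  expect_true(all(fit$history$mask_loss >= 0))
  expect_true(all(fit$history$mask_loss <= cfg$seq_len))
})

test_that("identical seeds reproduce identical trained weights", {
  task <- mini_task(epochs_per_class = 12L, n_channels = 2L)
  cfg <- config_for(task, n_layers = 1L, n_heads = 2L, d_model = 8L,
                    d_ff = 16L)
  sp <- train_spec(batch_size = 8L, max_epochs = 2L, seed = 9L)
  f1 <- train_model(task, cfg, sp)
  f2 <- train_model(task, cfg, sp)
  expect_identical(eegadapt:::flatten_params(f1$params),
                   eegadapt:::flatten_params(f2$params))
})

test_that("degenerate training inputs are refused", {
  task <- mini_task(epochs_per_class = 12L, n_channels = 2L)
  single <- task[task$labels == "alpha"]
  expect_error(train_model(single), "two classes")
  expect_error(train_model(task[c(1:5, 13:17)]), "10 epochs per class")
})

test_that("noise level 0 reproduces the clean evaluation exactly", {
  task <- mini_task(epochs_per_class = 12L, n_channels = 2L)
  cfg <- config_for(task, n_layers = 1L, n_heads = 2L, d_model = 8L,
                    d_ff = 16L)
  fit <- train_model(task, cfg, train_spec(batch_size = 8L, max_epochs = 2L,
                                           seed = 4L))
  test_ep <- task[fit$split$test]
  tab <- noise_robustness(fit, test_ep, levels = c(0, 50), seed = 3L)
  clean <- evaluate_model(fit, test_ep)
  expect_identical(tab$accuracy[1], clean$accuracy)
  expect_identical(nrow(tab), 2L)
  expect_error(noise_robustness(fit, test_ep, levels = numeric(0)), "empty")
})

test_that("a 1-cell ablation grid equals a direct train + evaluate", {
  task <- mini_task(epochs_per_class = 12L, n_channels = 2L)
  cfg <- config_for(task, n_layers = 1L, n_heads = 2L, d_model = 8L,
                    d_ff = 16L)
  sp <- train_spec(batch_size = 8L, max_epochs = 2L, seed = 6L)
  grid <- ablation_grid(task, heads = 2L, depths = 1L, lrs = sp$lr,
                        config = cfg, spec = sp)
  expect_identical(nrow(grid), 1L)
  direct_fit <- train_model(task, cfg, sp)
  direct <- evaluate_model(direct_fit, task[direct_fit$split$test])
  expect_equal(grid$accuracy, direct$accuracy)
  expect_equal(grid$f1, direct$f1)
  # grid row counting: |heads| x |depths| x |lrs|
  csv <- tempfile(fileext = ".csv")
  grid2 <- ablation_grid(task, heads = c(1L, 2L), depths = 1L,
                         lrs = c(0.001, 0.002), config = cfg, spec = sp,
                         csv_path = csv)
  expect_identical(nrow(grid2), 4L)
  expect_identical(nrow(read.csv(csv)), 4L)
  expect_error(ablation_grid(task, heads = integer(0)), "empty")
})

test_that("checkpoints round-trip weights, config and classes", {
  task <- mini_task(epochs_per_class = 12L, n_channels = 2L)
  cfg <- config_for(task, n_layers = 1L, n_heads = 2L, d_model = 8L,
                    d_ff = 16L)
  fit <- train_model(task, cfg, train_spec(batch_size = 8L, max_epochs = 1L,
                                           seed = 8L))
  f <- tempfile(fileext = ".ckpt")
  save_model(fit, f)
  back <- load_model(f)
  expect_identical(eegadapt:::flatten_params(back$params),
                   eegadapt:::flatten_params(fit$params))
  expect_identical(back$classes, fit$classes)
  p1 <- predict_model(fit, task[1:4])
  p2 <- predict_model(back, task[1:4])
  expect_identical(p1$probs, p2$probs)
})
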