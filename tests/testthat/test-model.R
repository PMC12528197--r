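# Transformer core: positional encoding, embedding, attention and mask
# algebra against hand oracles, stochasticity invariants, equivariance,
# and finite-difference gradient checks.

test_that("positional encoding matches its closed form", {
  pe <- positional_encoding(16, 256)
  expect_identical(dim(pe), c(16L, 256L))
  # pos = 0 row is (0, 1, 0, 1, ...)
  expect_equal(pe[1, ], rep(c(0, 1), 128))
  # direct scalar evaluation at a few (pos, i)
  for (pos in c(1L, 5L, 15L)) for (i in c(0L, 3L, 100L)) {
    expect_equal(pe[pos + 1, 2 * i + 1], sin(pos / 10000^(2 * i / 256)))
    expect_equal(pe[pos + 1, 2 * i + 2], cos(pos / 10000^(2 * i / 256)))
  }
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positional_encoding(4, 7), "even")
})

test_that("embedding is the linear map plus positional encoding", {
  set.seed(1)
  S <- matrix(rnorm(4 * 8), 4, 8)
  W <- matrix(rnorm(8 * 6), 8, 6)
  b <- rnorm(6)
  pe <- positional_encoding(4, 6)
  # zero map leaves exactly the positional encoding
  expect_equal(embed_frames(S, 0 * W, 0 * b, pe), pe, ignore_attr = TRUE)
  # zero frames leave bias + encoding
  expect_equal(embed_frames(0 * S, W, b, pe),
               matrix(b, 4, 6, byrow = TRUE) + pe, ignore_attr = TRUE)
  # linearity: doubling frames doubles (token - b - pe)
  t1 <- embed_frames(S, W, b, pe) - matrix(b, 4, 6, byrow = TRUE) - pe
  t2 <- embed_frames(2 * S, W, b, pe) - matrix(b, 4, 6, byrow = TRUE) - pe
  expect_equal(t2, 2 * t1)
  expect_error(embed_frames(S, matrix(1, 5, 6), b, pe), "match")
})

test_that("uniform scores give uniform attention and the identity mask is inert", {
  A <- attention_weights(matrix(0, 2, 4), matrix(0, 2, 4))
  expect_equal(A, matrix(0.5, 2, 2))
  M1 <- matrix(1, 2, 2)
  expect_identical(apply_adaptive_mask(A, M1), A)
})

test_that("masked attention matches a longhand 3x3 oracle", {
  set.seed(12)
  S3 <- matrix(rnorm(9), 3, 3)           # hand-set scores
  M3 <- matrix(runif(9, 0.1, 0.9), 3, 3)
  # oracle: softmax rows, elementwise product, renormalize, by explicit sums
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) {
    a <- oracle_softmax_row(S3[i, ])
    b <- a * M3[i, ]
    oracle[i, ] <- b / sum(b)
  }
  A <- softmax_rows(S3)
  expect_equal(apply_adaptive_mask(A, M3), oracle, tolerance = 1e-6)
})

test_that("fully masked rows fall back to the uniform distribution", {
  A <- softmax_rows(matrix(rnorm(9), 3, 3))
  M <- matrix(1, 3, 3); M[2, ] <- 0
  out <- apply_adaptive_mask(A, M)
  expect_equal(out[2, ], rep(1 / 3, 3))
  expect_equal(rowSums(out), rep(1, 3))
})

test_that("mask penalty matches Eq.-style brute force and its bounds", {
  set.seed(13)
  A <- softmax_rows(matrix(rnorm(16), 4, 4))
  M <- matrix(runif(16), 4, 4)
  brute <- 0
  for (i in 1:4) for (j in 1:4) brute <- brute + (1 - M[i, j]) * A[i, j]
  expect_equal(mask_penalty(A, M), brute)
  expect_equal(mask_penalty(A, matrix(1, 4, 4)), 0)
  expect_equal(mask_penalty(A, matrix(0, 4, 4)), 4)   # row count
  expect_error(mask_penalty(A, matrix(1, 3, 3)), "shapes differ")
})

test_that("spatial attention matches a 3-channel dot-product oracle", {
  set.seed(14)
  U <- matrix(rnorm(12), 3, 4)
  sa <- spatial_attention(U)
  e <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) e[i, j] <- sum(U[i, ] * U[j, ]) / sqrt(4)
  As <- t(apply(e, 1, oracle_softmax_row))
  expect_equal(sa$weights, As, tolerance = 1e-6)
  expect_equal(sa$pooled, colMeans(As %*% U))
  # identical summaries attend uniformly
  Uc <- matrix(rep(1:4, each = 3), 3, 4)
  expect_equal(spatial_attention(Uc)$weights, matrix(1 / 3, 3, 3))
  # single channel passes through
  expect_equal(spatial_attention(U[1, , drop = FALSE])$pooled, U[1, ])
})

test_that("classifier softmax matches closed forms", {
  expect_equal(classify_probs(c(1, 1), matrix(0, 2, 3), c(0, 0, 0)),
               rep(1 / 3, 3))
  p <- classify_probs(1, matrix(c(10, 0), 1, 2), c(0, 0))
  expect_equal(p[1], 1 / (1 + exp(-10)))
  set.seed(15)
  p2 <- classify_probs(rnorm(4), matrix(rnorm(8), 4, 2), rnorm(2))
  expect_equal(sum(p2), 1)
  expect_error(classify_probs(Inf, matrix(1, 1, 2), c(0, 0)), "non-finite")
})

test_that("forward output rows are probabilities and runs are deterministic", {
  cfg <- tiny_config()
  model <- init_model(cfg)
  fr <- tiny_frames(4, cfg)
  f1 <- transformer_forward(model, fr)
  f2 <- transformer_forward(model, fr)
  expect_equal(rowSums(f1$probs), rep(1, 4), tolerance = 1e-10)
  expect_identical(f1$probs, f2$probs)
  expect_error(transformer_forward(model, tiny_frames(2, tiny_config(seq_len = 8L))),
               "does not match")
})

test_that("attention rows are stochastic across random configurations", {
  set.seed(99)
  for (trial in 1:30) {
    P <- sample(2:5, 1); heads <- sample(1:2, 1)
    d <- heads * sample(c(2L, 4L), 1)
    C <- sample(1:3, 1)
    cfg <- tiny_config(n_channels = C, seq_len = P, frame_dim = 4L,
                       n_layers = 1L, n_heads = heads, d_model = d,
                       d_ff = 2L * d, seed = trial)
    model <- init_model(cfg)
    fr <- array(rnorm(2 * C * P * 4), c(2, C, P, 4))
    fw <- transformer_forward(model, fr, collect_attention = TRUE)
    at <- fw$attention$temporal[[1]]
    for (arr in list(at$raw, at$masked)) {
      sums <- apply(arr, c(1, 3, 4), sum)   # row sums over columns
      expect_true(all(abs(sums - 1) < 1e-6))
    }
    ssums <- apply(fw$attention$spatial, c(1, 3), sum)
    expect_true(all(abs(ssums - 1) < 1e-6))
  }
})

test_that("a fully open mask leaves the forward pass unmasked", {
  cfg <- tiny_config()
  model <- init_model(cfg)
  for (l in seq_along(model$params$layers))
    model$params$layers[[l]]$mask_logits[] <- 500   # sigmoid == 1 exactly
  fr <- tiny_frames(3, cfg)
  fw <- transformer_forward(model, fr, labels = c(1L, 2L, 1L),
                            collect_attention = TRUE)
  expect_identical(fw$mask_loss, 0)
  for (l in seq_along(fw$attention$temporal))
    expect_identical(fw$attention$temporal[[l]]$raw,
                     fw$attention$temporal[[l]]$masked)
  # op level: M = 1 output bit-equals the mask-free computation
  X <- matrix(rnorm(4 * 8), 4, 8)
  p <- model$params$layers[[1]]
  free <- temporal_self_attention(X, p$Wq, p$Wk, p$Wv, p$Wo, p$bo,
                                  M = NULL, n_heads = 2)
  ones <- temporal_self_attention(X, p$Wq, p$Wk, p$Wv, p$Wo, p$bo,
                                  M = matrix(1, 4, 4), n_heads = 2)
  expect_identical(free$output, ones$output)
})

test_that("a fully closed mask yields the row-count mask loss", {
  cfg <- tiny_config()
  model <- init_model(cfg)
  for (l in seq_along(model$params$layers))
    model$params$layers[[l]]$mask_logits[] <- -500  # sigmoid == 0 exactly
  fw <- transformer_forward(model, tiny_frames(2, cfg))
  expect_equal(fw$mask_loss, cfg$seq_len)
})

test_that("channel permutation leaves the pooled prediction invariant", {
  cfg <- tiny_config(n_channels = 3L)
  model <- init_model(cfg)
  fr <- tiny_frames(2, cfg)
  perm <- c(3L, 1L, 2L)
  f1 <- transformer_forward(model, fr)
  f2 <- transformer_forward(model, fr[, perm, , , drop = FALSE])
  expect_equal(f1$probs, f2$probs, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences for every block", {
  cfg <- tiny_config()
  model <- init_model(cfg)
  fr <- tiny_frames(3, cfg)
  y <- c(1L, 2L, 1L)
  fw <- transformer_forward(model, fr, labels = y, keep_cache = TRUE)
  g <- transformer_backward(model, fw$cache)
  loss_at <- function(params) {
    m <- model; m$params <- params
    transformer_forward(m, fr, labels = y)$loss
  }
  check_block <- function(get, set, gblock, n_probe = 5L) {
    vals <- as.numeric(get(model$params))
    gv <- as.numeric(gblock)
    set.seed(length(vals))
    probes <- sample(length(vals), min(n_probe, length(vals)))
    h <- 1e-5
    for (i in probes) {
      pp <- model$params
      vp <- vals; vp[i] <- vals[i] + h
      num_p <- loss_at(set(pp, vp))
      vm <- vals; vm[i] <- vals[i] - h
      num_m <- loss_at(set(pp, vm))
      num <- (num_p - num_m) / (2 * h)
      expect_lt(abs(num - gv[i]) / max(abs(num) + abs(gv[i]), 1e-8), 1e-4)
    }
  }
  restore <- function(field, l = NULL) {
    list(
      get = function(p) if (is.null(l)) p[[field]] else p$layers[[l]][[field]],
      set = function(p, v) {
        if (is.null(l)) p[[field]][] <- v else p$layers[[l]][[field]][] <- v
        p
      },
      g = if (is.null(l)) g[[field]] else g$layers[[l]][[field]])
  }
  blocks <- list(restore("W_emb"), restore("b_emb"),
                 restore("Wq", 1L), restore("Wk", 2L), restore("Wv", 1L),
                 restore("Wo", 2L), restore("mask_logits", 1L),
                 restore("mask_logits", 2L), restore("W1", 1L),
                 restore("W2", 2L), restore("b1", 1L),
                 restore("ln1_g", 1L), restore("ln2_b", 2L),
                 restore("lnf_g"), restore("W_cls"), restore("b_cls"))
  for (b in blocks) check_block(b$get, b$set, b$g)
})
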