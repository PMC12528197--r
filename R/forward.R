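# Transformer core, part 2: the batched forward pass. All B*C per-channel
# frame sequences are stacked into one (B*C*P) x d matrix so the linear
# maps run as single matrix products; per-sequence, per-head attention runs
# in a tight loop over tiny P x P matrices. A cache of intermediates is
# kept for the analytic backward pass.

ln_forward <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  n <- nrow(x); d <- ncol(x)
  list(y = xhat * matrix(g, n, d, byrow = TRUE) +
         matrix(b, n, d, byrow = TRUE),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  n <- nrow(dy); d <- ncol(dy)
  dxhat <- dy * matrix(g, n, d, byrow = TRUE)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

# stack frames (B,C,P,F) into a (B*C*P) x F matrix, sequence-major
stack_frames <- function(frames) {
  d <- dim(frames)
  matrix(aperm(frames, c(3L, 2L, 1L, 4L)), nrow = d[1L] * d[2L] * d[3L],
         ncol = d[4L])
}

# z-score each of the n sequences (blocks of P rows) over all its values
standardize_sequences <- function(Mf, n, P) {
  seq_id <- rep(seq_len(n), each = P)
  pf <- P * ncol(Mf)
  mu <- rowSums(rowsum(Mf, seq_id, reorder = FALSE)) / pf
  ss <- rowSums(rowsum(Mf * Mf, seq_id, reorder = FALSE)) / pf
  sd <- sqrt(pmax(ss - mu^2, 1e-12))
  (Mf - mu[seq_id]) / sd[seq_id]
}

#' Forward pass of the adaptive-attention transformer
#'
#' Runs embedding + positional encoding, the masked temporal encoder stack,
#' position pooling, spatial attention and the softmax head over a batch of
#' framed epochs. Deterministic when `training = FALSE` (dropout off).
#'
#' @param model an [init_model()] object.
#' @param frames array `B x C x P x F` of framed epochs (see
#'   [frame_epochs()]).
#' @param labels optional integer class labels (1..K) of length B; when
#'   given, cross-entropy and the total loss are computed.
#' @param training logical: apply dropout (uses the ambient RNG stream).
#' @param collect_attention logical: return all raw/masked temporal
#'   attention arrays and the spatial attention maps.
#' @param keep_cache logical: keep intermediates for [transformer_backward()].
#' @return list with `probs` (B x K), `pred` (integer class), `mask_loss`,
#'   `sparsity`, and -- when `labels` is given -- `ce` and `loss`
#'   (`ce + mask_lambda * mask_loss + mask_sparsity_lambda * sparsity`);
#'   optionally `attention` and `cache`.
#' @export
transformer_forward <- function(model, frames, labels = NULL,
                                training = FALSE, collect_attention = FALSE,
                                keep_cache = FALSE) {
  cfg <- model$config; prm <- model$params
  dm <- dim(frames)
  if (length(dm) != 4L)
    stop("`frames` must be a B x C x P x F array", call. = FALSE)
  B <- dm[1L]; C <- dm[2L]; P <- dm[3L]; Fd <- dm[4L]
  if (C != cfg$n_channels || P != cfg$seq_len || Fd != cfg$frame_dim)
    stop(sprintf(paste0("frame array (C=%d, P=%d, F=%d) does not match the ",
                        "model config (C=%d, P=%d, F=%d)"),
                 C, P, Fd, cfg$n_channels, cfg$seq_len, cfg$frame_dim),
         call. = FALSE)
  n <- B * C
  d <- cfg$d_model; H <- cfg$n_heads; dk <- d %/% H
  drop_p <- if (training) cfg$dropout else 0

  Mf <- stack_frames(frames)
  if (cfg$standardize) Mf <- standardize_sequences(Mf, n, P)
  pe <- positional_encoding(P, d)
  X <- Mf %*% prm$W_emb
  X <- X + matrix(prm$b_emb, nrow(X), d, byrow = TRUE) +
    pe[rep(seq_len(P), n), ]

  cache <- if (keep_cache) list(Mf = Mf, B = B, C = C, P = P, n = n) else NULL
  attn <- if (collect_attention) vector("list", cfg$n_layers) else NULL
  penalty <- 0; mask_mean <- 0

  for (l in seq_len(cfg$n_layers)) {
    ly <- prm$layers[[l]]
    lcache <- list()
    ln1 <- ln_forward(X, ly$ln1_g, ly$ln1_b)
    Q <- ln1$y %*% ly$Wq; K <- ln1$y %*% ly$Wk; V <- ln1$y %*% ly$Wv
    Ml <- 1 / (1 + exp(-ly$mask_logits))
    open_mask <- all(Ml == 1)   # exactly inert: skip the renormalization
    O <- matrix(0, n * P, d)
    A_arr <- array(0, c(P, P, H, n)); Ah_arr <- A_arr
    rs_arr <- array(0, c(P, H, n))
    for (s in seq_len(n)) {
      rows <- ((s - 1L) * P + 1L):(s * P)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        A <- attention_weights(Q[rows, cols, drop = FALSE],
                               K[rows, cols, drop = FALSE], dk)
        if (open_mask) {
          Ah <- A
          rs <- rep(1, P)
        } else {
          Bm <- A * Ml
          rs <- rowSums(Bm)
          safe <- rs > 1e-12
          Ah <- Bm / ifelse(safe, rs, 1)
          if (!all(safe)) Ah[!safe, ] <- 1 / P
        }
        O[rows, cols] <- Ah %*% V[rows, cols, drop = FALSE]
        A_arr[, , h, s] <- A; Ah_arr[, , h, s] <- Ah; rs_arr[, h, s] <- rs
        penalty <- penalty + sum((1 - Ml) * A)
      }
    }
    mask_mean <- mask_mean + mean(Ml)
    Oproj <- O %*% ly$Wo + matrix(ly$bo, n * P, d, byrow = TRUE)
    dmask1 <- NULL
    if (drop_p > 0) {
      dmask1 <- matrix(stats::rbinom(length(Oproj), 1L, 1 - drop_p),
                       nrow(Oproj), d) / (1 - drop_p)
      Oproj <- Oproj * dmask1
    }
    Xmid <- X + Oproj
    ln2 <- ln_forward(Xmid, ly$ln2_g, ly$ln2_b)
    H1 <- pmax(ln2$y %*% ly$W1 +
                 matrix(ly$b1, n * P, cfg$d_ff, byrow = TRUE), 0)
    Fo <- H1 %*% ly$W2 + matrix(ly$b2, n * P, d, byrow = TRUE)
    dmask2 <- NULL
    if (drop_p > 0) {
      dmask2 <- matrix(stats::rbinom(length(Fo), 1L, 1 - drop_p),
                       nrow(Fo), d) / (1 - drop_p)
      Fo <- Fo * dmask2
    }
    Xout <- Xmid + Fo
    if (keep_cache) {
      lcache$ln1 <- ln1[c("xhat", "inv")]
      lcache$Q <- Q; lcache$K <- K; lcache$V <- V; lcache$Xn1 <- ln1$y
      lcache$A_arr <- A_arr; lcache$Ah_arr <- Ah_arr; lcache$rs_arr <- rs_arr
      lcache$Ml <- Ml; lcache$O <- O; lcache$dmask1 <- dmask1
      lcache$ln2 <- ln2[c("xhat", "inv")]; lcache$Xn2 <- ln2$y
      lcache$H1 <- H1; lcache$dmask2 <- dmask2
      cache$layers[[l]] <- lcache
    }
    if (collect_attention)
      attn[[l]] <- list(raw = A_arr, masked = Ah_arr, mask = Ml)
    X <- Xout
  }

  lnf <- ln_forward(X, prm$lnf_g, prm$lnf_b)
  seq_id <- rep(seq_len(n), each = P)
  U <- rowsum(lnf$y, seq_id, reorder = FALSE) / P        # n x d summaries
  Hpool <- matrix(0, B, d)
  As_arr <- array(0, c(C, C, B))
  for (b in seq_len(B)) {
    sb <- ((b - 1L) * C + 1L):(b * C)
    sa <- spatial_attention(U[sb, , drop = FALSE])
    Hpool[b, ] <- sa$pooled
    As_arr[, , b] <- sa$weights
  }
  logits <- Hpool %*% prm$W_cls +
    matrix(prm$b_cls, B, cfg$n_classes, byrow = TRUE)
  probs <- softmax_rows(logits)

  mask_loss <- penalty / (cfg$n_layers * H * n)
  sparsity <- mask_mean / cfg$n_layers
  out <- list(probs = probs, pred = max.col(probs, ties.method = "first"),
              mask_loss = mask_loss, sparsity = sparsity)
  if (!is.null(labels)) {
    if (length(labels) != B) stop("one label per epoch required", call. = FALSE)
    out$ce <- -mean(log(pmax(probs[cbind(seq_len(B), labels)], 1e-300)))
    out$loss <- out$ce + cfg$mask_lambda * mask_loss +
      cfg$mask_sparsity_lambda * sparsity
  }
  if (collect_attention) {
    out$attention <- list(temporal = attn, spatial = As_arr)
  }
  if (keep_cache) {
    cache$lnf <- lnf[c("xhat", "inv")]
    cache$Xf <- lnf$y; cache$U <- U; cache$As_arr <- As_arr
    cache$Hpool <- Hpool; cache$probs <- probs; cache$labels <- labels
    out$cache <- cache
  }
  out
}
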