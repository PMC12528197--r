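# Transformer core, part 1: configuration, parameter initialisation, and the
# attention primitives. The model embeds per-channel frame sequences
# linearly, adds sinusoidal positional encodings, runs a pre-norm encoder
# stack whose attention weights are gated by a learned adaptive mask
# M = sigmoid(logits) in (0,1), pools positions, mixes channels with
# dot-product spatial attention, and classifies with a softmax head. The
# mask is trained with a retention penalty sum((1 - M) * A) plus a
# magnitude regularizer, so it learns to down-weight attention the task
# does not need.

#' Transformer model configuration
#'
#' Defaults follow the reference architecture: 6 encoder layers, 8 heads,
#' 256-dimensional embeddings, FFN width `4 * d_model`. The ablation grid
#' uses heads in \{4, 8, 12\} and depth in \{3, 6\}.
#'
#' @param n_classes number of classes K (>= 2).
#' @param n_channels EEG channel count C.
#' @param seq_len frames per epoch P (default 16).
#' @param frame_dim input dimension of one frame (raw samples per frame, or
#'   5 for band-power frames).
#' @param n_layers encoder depth (default 6).
#' @param n_heads attention heads (default 8); must divide `d_model`.
#' @param d_model embedding size (default 256); must be even.
#' @param d_ff feed-forward hidden width (default `4 * d_model`).
#' @param mask_lambda weight of the mask retention penalty in the total
#'   loss (default 0.1).
#' @param mask_sparsity_lambda weight of the mask magnitude regularizer
#'   `mean(M)` (default 0.01); without it the retention penalty alone is
#'   minimized by the degenerate `M == 1`.
#' @param dropout dropout rate on sublayer outputs during training.
#' @param layout frame layout fed to the model (see [frame_epochs()]).
#' @param standardize z-score each epoch-channel frame sequence before
#'   embedding.
#' @param seed integer seed for parameter initialisation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_classes, n_channels, seq_len = 16L, frame_dim = 32L,
                         n_layers = 6L, n_heads = 8L, d_model = 256L,
                         d_ff = 4L * d_model, mask_lambda = 0.1,
                         mask_sparsity_lambda = 0.01, dropout = 0.1,
                         layout = c("raw_frames", "band_frames"),
                         standardize = TRUE, seed = 1L) {
  layout <- match.arg(layout)
  if (n_classes < 2L) stop("need at least two classes", call. = FALSE)
  if (d_model %% n_heads != 0L)
    stop("d_model (", d_model, ") must be divisible by n_heads (", n_heads,
         ")", call. = FALSE)
  if (d_model %% 2L != 0L)
    stop("d_model must be even for the sinusoidal positional encoding",
         call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels),
                 seq_len = as.integer(seq_len), frame_dim = as.integer(frame_dim),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 mask_lambda = mask_lambda,
                 mask_sparsity_lambda = mask_sparsity_lambda,
                 dropout = dropout, layout = layout,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "model_config")
}

#' Sinusoidal positional encoding
#'
#' Row `pos` (0-based) has `sin(pos / 10000^(2i/d))` in even 0-based
#' dimensions `2i` and `cos(pos / 10000^(2i/d))` in odd dimensions `2i + 1`.
#' The `pos = 0` row is therefore exactly (0, 1, 0, 1, ...).
#'
#' @param seq_len number of positions.
#' @param d_model embedding size (even).
#' @return A `seq_len x d_model` matrix with entries in \[-1, 1\].
#' @export
positional_encoding <- function(seq_len, d_model) {
  if (d_model %% 2L != 0L) stop("d_model must be even", call. = FALSE)
  pos <- seq_len(seq_len) - 1L
  i <- seq_len(d_model %/% 2L) - 1L
  ang <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, seq_len, d_model)
  pe[, 2L * i + 1L] <- sin(ang)
  pe[, 2L * i + 2L] <- cos(ang)
  pe
}

#' Row-wise softmax
#'
#' @param m numeric matrix.
#' @return Matrix of the same shape with each row a probability vector.
#' @export
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Raw temporal attention weights
#'
#' `softmax(Q K^T / sqrt(d_k))`, computed row-wise.
#'
#' @param Q,K query/key matrices (P x d_k).
#' @param d_k key dimension used in the scaling (default `ncol(K)`).
#' @return A row-stochastic P x P matrix.
#' @export
attention_weights <- function(Q, K, d_k = ncol(K)) {
  softmax_rows(tcrossprod(Q, K) / sqrt(d_k))
}

#' Apply an adaptive mask to attention weights
#'
#' Elementwise product `A * M` followed by row renormalization, so the
#' masked weights remain a convex combination over value vectors. A row
#' whose retained mass falls below `1e-12` (fully masked) falls back to the
#' uniform distribution.
#'
#' @param A row-stochastic attention weights (P x P).
#' @param M mask matrix with entries in (0, 1), same shape.
#' @return A row-stochastic matrix of masked, renormalized weights.
#' @export
apply_adaptive_mask <- function(A, M) {
  if (!identical(dim(A), dim(M)))
    stop("mask and attention shapes differ", call. = FALSE)
  if (all(M == 1)) return(A)   # fully open mask is exactly inert
  B <- A * M
  rs <- rowSums(B)
  safe <- rs > 1e-12
  out <- B / ifelse(safe, rs, 1)
  if (!all(safe)) out[!safe, ] <- 1 / ncol(A)
  out
}

#' Mask retention penalty
#'
#' `sum((1 - M) * A)`: attention mass retained in regions the mask
#' down-weights. Zero when `M == 1` everywhere; equal to the number of rows
#' of a row-stochastic `A` when `M == 0`.
#'
#' @param A row-stochastic attention weights.
#' @param M mask matrix, same shape.
#' @return Non-negative scalar.
#' @export
mask_penalty <- function(A, M) {
  if (!identical(dim(A), dim(M)))
    stop("mask and attention shapes differ", call. = FALSE)
  sum((1 - M) * A)
}

#' Masked multi-head temporal self-attention over one token sequence
#'
#' Splits `d_model` into `n_heads` subspaces, computes per-head raw weights
#' `softmax(Q K^T / sqrt(d_k))`, gates them with the adaptive mask
#' (renormalized), mixes values, and recombines heads through the output
#' projection.
#'
#' @param X token matrix (P x d_model).
#' @param Wq,Wk,Wv,Wo projection matrices (d_model x d_model).
#' @param bo output bias (length d_model).
#' @param M adaptive mask (P x P); `NULL` means no masking.
#' @param n_heads number of heads.
#' @return list with `output` (P x d_model), `raw` and `masked` (P x P x
#'   n_heads arrays of attention weights).
#' @export
temporal_self_attention <- function(X, Wq, Wk, Wv, Wo, bo, M = NULL,
                                    n_heads = 1L) {
  d <- ncol(X); P <- nrow(X)
  if (d %% n_heads != 0L) stop("n_heads must divide d_model", call. = FALSE)
  dk <- d %/% n_heads
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  O <- matrix(0, P, d)
  raw <- array(0, c(P, P, n_heads)); masked <- raw
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    A <- attention_weights(Q[, cols, drop = FALSE], K[, cols, drop = FALSE], dk)
    Ah <- if (is.null(M)) A else apply_adaptive_mask(A, M)
    O[, cols] <- Ah %*% V[, cols, drop = FALSE]
    raw[, , h] <- A; masked[, , h] <- Ah
  }
  list(output = O %*% Wo + matrix(bo, P, d, byrow = TRUE),
       raw = raw, masked = masked)
}

#' Dot-product spatial attention over channel summaries
#'
#' Similarity `e_ij = u_i . u_j / sqrt(d)` between channel summary vectors,
#' row-softmax to spatial weights, then mean over channels of the attended
#' summaries gives one pooled vector.
#'
#' @param U channel summary matrix (C x d).
#' @return list with `weights` (row-stochastic C x C) and `pooled`
#'   (length-d vector).
#' @export
spatial_attention <- function(U) {
  if (!is.matrix(U) || nrow(U) < 1L)
    stop("need at least one channel summary", call. = FALSE)
  As <- softmax_rows(tcrossprod(U) / sqrt(ncol(U)))
  list(weights = As, pooled = colMeans(As %*% U))
}

#' Softmax classification probabilities
#'
#' @param h pooled hidden vector (length d).
#' @param W class weight matrix (d x K).
#' @param b class bias (length K).
#' @return Probability vector of length K (sums to 1).
#' @export
classify_probs <- function(h, W, b) {
  logits <- drop(h %*% W) + b
  if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
  as.vector(softmax_rows(matrix(logits, 1L)))
}

#' Embed a per-channel frame sequence
#'
#' Linear map of each frame to the model dimension plus the sinusoidal
#' positional encoding: `token_p = W' s_p + b + pe_p`.
#'
#' @param S frame matrix (P x frame_dim), one row per position.
#' @param W embedding weights (frame_dim x d_model).
#' @param b embedding bias (length d_model).
#' @param pe positional encoding matrix (P x d_model), e.g.
#'   [positional_encoding()]; `NULL` to skip.
#' @return Token matrix (P x d_model).
#' @export
embed_frames <- function(S, W, b, pe = NULL) {
  if (ncol(S) != nrow(W))
    stop("frame dimension does not match embedding weights", call. = FALSE)
  out <- S %*% W + matrix(b, nrow(S), ncol(W), byrow = TRUE)
  if (!is.null(pe)) out <- out + pe
  out
}

glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

#' Initialise a transformer model
#'
#' Parameters are drawn with Glorot-uniform scaling from `config$seed`; the
#' embedding is shared across channels, the adaptive mask logits are
#' per-layer (shared across heads) and start at 2 (`sigmoid(2) ~ 0.88`, a
#' nearly open mask), and layer norms start at identity.
#'
#' @param config a [model_config()].
#' @return An object of class `eeg_transformer`: list with `params`,
#'   `config`, `classes` (label names, filled at training time).
#' @export
init_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d <- config$d_model; P <- config$seq_len
  with_local_seed(config$seed, {
    params <- list(
      W_emb = glorot(config$frame_dim, d), b_emb = numeric(d),
      layers = lapply(seq_len(config$n_layers), function(l) list(
        ln1_g = rep(1, d), ln1_b = numeric(d),
        Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
        Wo = glorot(d, d), bo = numeric(d),
        mask_logits = matrix(2, P, P),
        ln2_g = rep(1, d), ln2_b = numeric(d),
        W1 = glorot(d, config$d_ff), b1 = numeric(config$d_ff),
        W2 = glorot(config$d_ff, d), b2 = numeric(d))),
      lnf_g = rep(1, d), lnf_b = numeric(d),
      W_cls = glorot(d, config$n_classes), b_cls = numeric(config$n_classes))
    structure(list(params = params, config = config, classes = NULL),
              class = "eeg_transformer")
  })
}

#' @export
print.eeg_transformer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<eeg_transformer> %d layers, %d heads, d_model %d, ",
                     "P %d, %d channels, %d classes (%s)\n"),
              cfg$n_layers, cfg$n_heads, cfg$d_model, cfg$seq_len,
              cfg$n_channels, cfg$n_classes,
              if (is.null(x$classes)) "untrained"
              else paste(x$classes, collapse = " vs ")))
  invisible(x)
}

# flatten / restore nested numeric parameter lists (Adam, gradient checks)
flatten_params <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, flatten_params), use.names = FALSE)
}

unflatten_params <- function(template, v, pos = 1L) {
  if (is.numeric(template)) {
    n <- length(template)
    out <- v[pos:(pos + n - 1L)]
    attributes(out) <- attributes(template)
    return(list(value = out, pos = pos + n))
  }
  res <- template
  for (k in seq_along(template)) {
    r <- unflatten_params(template[[k]], v, pos)
    res[[k]] <- r$value
    pos <- r$pos
  }
  list(value = res, pos = pos)
}

zero_like <- function(p) {
  if (is.numeric(p)) {
    z <- p; z[] <- 0; return(z)
  }
  lapply(p, zero_like)
}
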