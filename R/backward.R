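# Transformer core, part 3: analytic reverse-mode gradients of the total
# loss (cross-entropy + mask_lambda * retention penalty + sparsity
# regularizer) with respect to every learnable tensor. Mirrors the forward
# cache layer by layer; correctness is guarded by finite-difference tests.

#' Backward pass of the adaptive-attention transformer
#'
#' Computes the gradient of the total training loss for the batch that
#' produced `cache` (from [transformer_forward()] with `keep_cache = TRUE`
#' and `labels`).
#'
#' @param model the model used in the forward pass.
#' @param cache forward cache.
#' @return A gradient list with the same structure as `model$params`.
#' @export
transformer_backward <- function(model, cache) {
  cfg <- model$config; prm <- model$params
  B <- cache$B; C <- cache$C; P <- cache$P; n <- cache$n
  d <- cfg$d_model; H <- cfg$n_heads; dk <- d %/% H
  K_cls <- cfg$n_classes
  labels <- cache$labels
  if (is.null(labels)) stop("cache was built without labels", call. = FALSE)
  g <- zero_like(prm)

  # classifier head
  Y <- matrix(0, B, K_cls); Y[cbind(seq_len(B), labels)] <- 1
  dlogits <- (cache$probs - Y) / B
  g$W_cls <- crossprod(cache$Hpool, dlogits)
  g$b_cls <- colSums(dlogits)
  dHpool <- tcrossprod(dlogits, prm$W_cls)

  # spatial attention pooling
  dU <- matrix(0, n, d)
  sdm <- sqrt(d)
  for (b in seq_len(B)) {
    sb <- ((b - 1L) * C + 1L):(b * C)
    Ub <- cache$U[sb, , drop = FALSE]
    As <- matrix(cache$As_arr[, , b], C, C)
    dZ <- matrix(dHpool[b, ] / C, C, d, byrow = TRUE)
    dAs <- tcrossprod(dZ, Ub)
    dUb <- crossprod(As, dZ)
    de <- As * (dAs - rowSums(dAs * As))
    dUb <- dUb + (de + t(de)) %*% Ub / sdm
    dU[sb, ] <- dUb
  }

  # position pooling and final layer norm
  dXf <- dU[rep(seq_len(n), each = P), , drop = FALSE] / P
  lb <- ln_backward(dXf, cache$lnf, prm$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dx

  coefm <- cfg$mask_lambda / (cfg$n_layers * H * n)
  coefs <- cfg$mask_sparsity_lambda / (cfg$n_layers * P * P)

  for (l in rev(seq_len(cfg$n_layers))) {
    ly <- prm$layers[[l]]; lc <- cache$layers[[l]]
    gl <- g$layers[[l]]

    # FFN sublayer (residual: Xout = Xmid + dropout(FFN(LN2(Xmid))))
    dFo <- if (is.null(lc$dmask2)) dX else dX * lc$dmask2
    gl$W2 <- crossprod(lc$H1, dFo)
    gl$b2 <- colSums(dFo)
    dH1 <- tcrossprod(dFo, ly$W2) * (lc$H1 > 0)
    gl$W1 <- crossprod(lc$Xn2, dH1)
    gl$b1 <- colSums(dH1)
    dXn2 <- tcrossprod(dH1, ly$W1)
    lb2 <- ln_backward(dXn2, lc$ln2, ly$ln2_g)
    gl$ln2_g <- lb2$dg; gl$ln2_b <- lb2$db
    dXmid <- dX + lb2$dx

    # attention sublayer
    dOproj <- if (is.null(lc$dmask1)) dXmid else dXmid * lc$dmask1
    gl$Wo <- crossprod(lc$O, dOproj)
    gl$bo <- colSums(dOproj)
    dO <- tcrossprod(dOproj, ly$Wo)
    dQ <- matrix(0, n * P, d); dK <- dQ; dV <- dQ
    dMl <- matrix(0, P, P)
    Ml <- lc$Ml
    oneMl <- 1 - Ml
    for (s in seq_len(n)) {
      rows <- ((s - 1L) * P + 1L):(s * P)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        A <- matrix(lc$A_arr[, , h, s], P, P)
        Ah <- matrix(lc$Ah_arr[, , h, s], P, P)
        rs <- lc$rs_arr[, h, s]
        dOs <- dO[rows, cols, drop = FALSE]
        dAh <- tcrossprod(dOs, lc$V[rows, cols, drop = FALSE])
        dV[rows, cols] <- crossprod(Ah, dOs)
        # renormalization backward (zero gradient through uniform fallback)
        safe <- rs > 1e-12
        dB <- (dAh - rowSums(dAh * Ah)) / ifelse(safe, rs, 1)
        if (!all(safe)) dB[!safe, ] <- 0
        dA <- dB * Ml + coefm * oneMl
        dMl <- dMl + dB * A - coefm * A
        dS <- A * (dA - rowSums(dA * A))
        Qs <- lc$Q[rows, cols, drop = FALSE]
        Ks <- lc$K[rows, cols, drop = FALSE]
        dQ[rows, cols] <- dS %*% Ks / sqrt(dk)
        dK[rows, cols] <- crossprod(dS, Qs) / sqrt(dk)
      }
    }
    gl$mask_logits <- (dMl + coefs) * Ml * oneMl
    gl$Wq <- crossprod(lc$Xn1, dQ)
    gl$Wk <- crossprod(lc$Xn1, dK)
    gl$Wv <- crossprod(lc$Xn1, dV)
    dXn1 <- tcrossprod(dQ, ly$Wq) + tcrossprod(dK, ly$Wk) +
      tcrossprod(dV, ly$Wv)
    lb1 <- ln_backward(dXn1, lc$ln1, ly$ln1_g)
    gl$ln1_g <- lb1$dg; gl$ln1_b <- lb1$db
    dX <- dXmid + lb1$dx
    g$layers[[l]] <- gl
  }

  g$W_emb <- crossprod(cache$Mf, dX)
  g$b_emb <- colSums(dX)
  g
}
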