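# Analytic gradients of the summed cross-entropy through the whole network,
# document by document. The traversal mirrors forward_doc(); `g` is a
# gradient accumulator with the same shape as model$params and is returned
# with this document's contribution added. Verified against central finite
# differences (see the gradient tests).

act_deriv <- function(pre, out, act) {
  switch(act, tanh = 1 - out^2, relu = as.numeric(pre > 0),
         identity = rep(1, length(pre)))
}

# BPTT for one LSTM direction. Xr, cacheL and dh_seq are in processing
# order; returns parameter gradients and the gradient w.r.t. Xr.
lstm_backward <- function(par, Xr, cacheL, dh_seq) {
  Tn <- nrow(Xr)
  H <- ncol(cacheL$h)
  i1 <- 1:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H)
  i4 <- (3L * H + 1L):(4L * H)
  gW <- matrix(0, 4L * H, ncol(Xr))
  gU <- matrix(0, 4L * H, H)
  gb <- numeric(4L * H)
  dX <- matrix(0, Tn, ncol(Xr))
  dh_carry <- numeric(H)
  dc_carry <- numeric(H)
  for (t in Tn:1) {
    gt <- cacheL$gates[t, ]
    ig <- gt[i1]; fg <- gt[i2]; gg <- gt[i3]; og <- gt[i4]
    tc <- tanh(cacheL$c[t, ])
    dh <- dh_seq[t, ] + dh_carry
    do_ <- dh * tc
    dc <- dc_carry + dh * og * (1 - tc^2)
    cprev <- if (t > 1L) cacheL$c[t - 1L, ] else numeric(H)
    hprev <- if (t > 1L) cacheL$h[t - 1L, ] else numeric(H)
    da <- c(dc * gg * ig * (1 - ig),
            dc * cprev * fg * (1 - fg),
            dc * ig * (1 - gg^2),
            do_ * og * (1 - og))
    gW <- gW + outer(da, Xr[t, ])
    gU <- gU + outer(da, hprev)
    gb <- gb + da
    dh_carry <- as.vector(crossprod(par$U, da))
    dc_carry <- dc * fg
    dX[t, ] <- as.vector(crossprod(par$W, da))
  }
  list(W = gW, U = gU, b = gb, dX = dX)
}

backward_doc <- function(model, cache, y, g) {
  ctl <- model$control; P <- model$params; vs <- model$vspec; dm <- model$dims
  Treal <- cache$Treal
  d <- dm$d; H <- dm$H; j <- dm$j
  zC <- cache$pool$z; zB <- cache$cs$zB

  df <- cache$p
  df[y] <- df[y] - 1            # d(-log p_y)/d f

  d_lr <- NULL; d_lw <- NULL; d_pF <- NULL
  if (vs$middle) {
    pF <- cache$pF
    if (vs$triple) {
      u <- c(zC, zB, pF)
      g$head_T$W <- g$head_T$W + outer(df, u)
      g$head_T$b <- g$head_T$b + df
      du <- as.vector(crossprod(P$head_T$W, df))
      d_zC <- du[seq_len(dm$zc)]
      d_zB <- du[dm$zc + seq_len(dm$zb)]
      d_pF <- du[dm$zc + dm$zb + seq_len(dm$p)]
    } else {
      wts <- c(ctl$alpha, (1 - ctl$alpha) / 2, (1 - ctl$alpha) / 2)
      dC <- wts[1] * df; dB <- wts[2] * df; dF <- wts[3] * df
      g$head_C$W <- g$head_C$W + outer(dC, c(zC, pF))
      g$head_C$b <- g$head_C$b + dC
      g$head_B$W <- g$head_B$W + outer(dB, c(zB, pF))
      g$head_B$b <- g$head_B$b + dB
      g$head_F$W <- g$head_F$W + outer(dF, pF)
      g$head_F$b <- g$head_F$b + dF
      dUC <- as.vector(crossprod(P$head_C$W, dC))
      dUB <- as.vector(crossprod(P$head_B$W, dB))
      d_zC <- dUC[seq_len(dm$zc)]
      d_zB <- dUB[seq_len(dm$zb)]
      d_pF <- dUC[dm$zc + seq_len(dm$p)] + dUB[dm$zb + seq_len(dm$p)] +
        as.vector(crossprod(P$head_F$W, dF))
    }
    dpre <- d_pF * act_deriv(cache$fus$pre, pF, ctl$mlp_activation)
    g$fuse$W <- g$fuse$W + outer(dpre, cache$fus$lF)
    g$fuse$b <- g$fuse$b + dpre
    dlF <- as.vector(crossprod(P$fuse$W, dpre))
    d_lr <- dlF[seq_len(dm$zc)]
    d_lw <- dlF[dm$zc + seq_len(dm$zb)]
  } else {
    dC <- ctl$alpha * df; dB <- (1 - ctl$alpha) * df
    g$head_C$W <- g$head_C$W + outer(dC, zC)
    g$head_C$b <- g$head_C$b + dC
    g$head_B$W <- g$head_B$W + outer(dB, zB)
    g$head_B$b <- g$head_B$b + dB
    d_zC <- as.vector(crossprod(P$head_C$W, dC))
    d_zB <- as.vector(crossprod(P$head_B$W, dB))
  }

  dX <- matrix(0, length(cache$ids), d)

  # ---- right branch ----
  dH_seq <- matrix(0, Treal, dm$zb)
  if (!is.null(d_lw)) {
    Hr <- cache$enc$Hseq[seq_len(Treal), , drop = FALSE]
    if (vs$word_attn) {
      wa <- P$wattn; att <- cache$wattn
      dalpha <- as.vector(Hr %*% d_lw)
      ds <- att$alpha * (dalpha - sum(att$alpha * dalpha))
      dU <- outer(ds, wa$u)
      g$wattn$u <- g$wattn$u + as.vector(crossprod(att$U, ds))
      dq <- dU * (1 - att$U^2)
      g$wattn$W <- g$wattn$W + crossprod(dq, Hr)
      g$wattn$b <- g$wattn$b + colSums(dq)
      dH_seq <- dH_seq + dq %*% wa$W + outer(att$alpha, d_lw)
    } else {
      dH_seq <- dH_seq + matrix(d_lw / Treal, Treal, dm$zb, byrow = TRUE)
    }
  }
  dhf <- dH_seq[, seq_len(H), drop = FALSE]          # document order
  dhb_doc <- dH_seq[, H + seq_len(H), drop = FALSE]
  if (ctl$context_summary == "final") {
    dhf[Treal, ] <- dhf[Treal, ] + d_zB[seq_len(H)]
    dhb_doc[1L, ] <- dhb_doc[1L, ] + d_zB[H + seq_len(H)]
  } else {
    idx <- cbind(cache$cs$argmax, seq_len(dm$zb))
    dHz <- matrix(0, Treal, dm$zb)
    dHz[idx] <- d_zB
    dhf <- dhf + dHz[, seq_len(H), drop = FALSE]
    dhb_doc <- dhb_doc + dHz[, H + seq_len(H), drop = FALSE]
  }
  Xr <- cache$X[seq_len(Treal), , drop = FALSE]
  bf <- lstm_backward(P$lstm_f, Xr, cache$enc$fwd, dhf)
  g$lstm_f$W <- g$lstm_f$W + bf$W
  g$lstm_f$U <- g$lstm_f$U + bf$U
  g$lstm_f$b <- g$lstm_f$b + bf$b
  dX[seq_len(Treal), ] <- dX[seq_len(Treal), ] + bf$dX
  Xrev <- Xr[Treal:1, , drop = FALSE]
  bb <- lstm_backward(P$lstm_b, Xrev, cache$enc$bwd,
                      dhb_doc[Treal:1, , drop = FALSE])
  g$lstm_b$W <- g$lstm_b$W + bb$W
  g$lstm_b$U <- g$lstm_b$U + bb$U
  g$lstm_b$b <- g$lstm_b$b + bb$b
  dX[seq_len(Treal), ] <- dX[seq_len(Treal), ] + bb$dX[Treal:1, , drop = FALSE]

  # ---- left branch ----
  for (hi in seq_along(cache$maps)) {
    m <- cache$maps[[hi]]
    k <- m$k
    N <- nrow(m$Z)
    zoff <- (hi - 1L) * j
    dZ <- matrix(0, N, j)
    am <- cache$pool$argmax[[hi]]
    idx <- cbind(am, seq_len(j))
    dZ[idx] <- dZ[idx] + d_zC[zoff + seq_len(j)]
    if (!is.null(d_lr)) {
      dlr_k <- d_lr[zoff + seq_len(j)]
      if (vs$phrase_attn) {
        pa_i <- if (ctl$share_phrase_attn) 1L else hi
        pa <- P$pattn[[pa_i]]
        att <- cache$pattn[[hi]]
        vi <- att$valid_idx
        Zv <- m$Z[vi, , drop = FALSE]
        bv <- att$beta[vi]
        dbeta <- as.vector(Zv %*% dlr_k)
        ds <- bv * (dbeta - sum(bv * dbeta))
        dV <- outer(ds, pa$u)
        g$pattn[[pa_i]]$u <- g$pattn[[pa_i]]$u + as.vector(crossprod(att$V, ds))
        dq <- dV * (1 - att$V^2)
        g$pattn[[pa_i]]$W <- g$pattn[[pa_i]]$W + crossprod(dq, Zv)
        g$pattn[[pa_i]]$b <- g$pattn[[pa_i]]$b + colSums(dq)
        dZ[vi, ] <- dZ[vi, ] + dq %*% pa$W + outer(bv, dlr_k)
      } else {
        vi <- which(m$valid)
        dZ[vi, ] <- dZ[vi, ] +
          matrix(dlr_k / length(vi), length(vi), j, byrow = TRUE)
      }
    }
    dZpre <- if (ctl$conv_activation == "relu") dZ * (m$Zpre > 0) else dZ
    g$conv[[hi]]$W <- g$conv[[hi]]$W + crossprod(dZpre, m$A)
    g$conv[[hi]]$b <- g$conv[[hi]]$b + colSums(dZpre)
    dA <- dZpre %*% P$conv[[hi]]$W
    for (s in 0:(k - 1L))
      dX[(1L + s):(N + s), ] <- dX[(1L + s):(N + s), ] +
        dA[, s * d + seq_len(d), drop = FALSE]
  }

  # ---- dropout and embedding ----
  if (!is.null(cache$drop_mask)) dX <- dX * cache$drop_mask
  realt <- which(cache$mask)
  if (length(realt)) {
    agg <- rowsum(dX[realt, , drop = FALSE], group = cache$ids[realt])
    cols <- as.integer(rownames(agg))
    g$emb[, cols] <- g$emb[, cols] + t(agg)
  }
  g
}
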