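# Layer primitives. Each works on one document (T small) with an explicit
# mask so padded positions never leak into convolution pooling, attention or
# the recurrent summary. All are deterministic; dropout is drawn once per
# document in forward_doc() during training only.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_stable <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

log_softmax_stable <- function(x) {
  m <- max(x)
  x - m - log(sum(exp(x - m)))
}

# Embedding lookup x_t = He_t as a column gather; pad rows come out zero
# because the pad column of the table is held at zero.
embed_doc <- function(ids, emb, pad_id) {
  X <- t(emb[, ids, drop = FALSE])
  list(X = X, mask = ids != pad_id)
}

# Narrow (valid) convolution, stride 1: row i of Z holds the j filter
# responses on words i..i+k-1. A filter's width equals the embedding
# dimension, so each response is one inner product with the unrolled window.
conv_feature_map <- function(X, mask, W, b, k, activation = "relu") {
  Tlen <- nrow(X)
  if (Tlen < k) stop("sequence shorter than filter height ", k, call. = FALSE)
  N <- Tlen - k + 1L
  A <- do.call(cbind, lapply(0:(k - 1L), function(s)
    X[(1L + s):(N + s), , drop = FALSE]))
  Zpre <- A %*% t(W) + matrix(b, N, nrow(W), byrow = TRUE)
  Z <- if (activation == "relu") pmax(Zpre, 0) else Zpre
  # a row is valid when its window covers only real tokens; a document
  # shorter than k keeps its single all-covering window (pad rows are zero)
  win_real <- vapply(seq_len(N), function(i) all(mask[i:(i + k - 1L)]), logical(1))
  if (!any(win_real)) win_real[1L] <- TRUE
  list(k = k, Z = Z, Zpre = Zpre, A = A, valid = win_real)
}

# Per-filter max over valid rows of each map, concatenated in height order.
max_pool_concat <- function(maps) {
  pooled <- lapply(maps, function(m) {
    vi <- which(m$valid)
    Zv <- m$Z[vi, , drop = FALSE]
    am <- vi[apply(Zv, 2L, which.max)]
    list(z = apply(Zv, 2L, max), argmax = am)
  })
  list(z = unlist(lapply(pooled, `[[`, "z"), use.names = FALSE),
       argmax = lapply(pooled, `[[`, "argmax"))
}

# Additive attention over the valid rows of one feature map:
# v_i = tanh(W_r Z_i + b_r), beta = softmax(v_i . u_p), l_r = sum beta_i Z_i.
phrase_attend <- function(map, pa) {
  vi <- which(map$valid)
  Zv <- map$Z[vi, , drop = FALSE]
  V <- tanh(Zv %*% t(pa$W) + matrix(pa$b, length(vi), length(pa$b), byrow = TRUE))
  s <- as.vector(V %*% pa$u)
  beta_v <- softmax_stable(s)
  beta <- numeric(nrow(map$Z))
  beta[vi] <- beta_v
  list(beta = beta, lr = as.vector(crossprod(Zv, beta_v)), V = V,
       scores = s, valid_idx = vi)
}

masked_mean_rows <- function(M, idx) {
  colMeans(M[idx, , drop = FALSE])
}

# One direction of the LSTM over rows of Xr (already in processing order).
# Gate order i, f, g, o; standard cell: c_t = f*c_{t-1} + i*g, h_t = o*tanh(c_t).
lstm_run <- function(par, Xr) {
  H <- length(par$b) %/% 4L
  Tn <- nrow(Xr)
  Wx <- Xr %*% t(par$W)
  hs <- matrix(0, Tn, H)
  cs <- matrix(0, Tn, H)
  gates <- matrix(0, Tn, 4L * H)
  h <- numeric(H)
  cprev <- numeric(H)
  i1 <- 1:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H)
  i4 <- (3L * H + 1L):(4L * H)
  for (t in seq_len(Tn)) {
    a <- Wx[t, ] + as.vector(par$U %*% h) + par$b
    ig <- sigmoid(a[i1]); fg <- sigmoid(a[i2])
    gg <- tanh(a[i3]); og <- sigmoid(a[i4])
    cnew <- fg * cprev + ig * gg
    h <- og * tanh(cnew)
    hs[t, ] <- h; cs[t, ] <- cnew; gates[t, ] <- c(ig, fg, gg, og)
    cprev <- cnew
  }
  list(h = hs, c = cs, gates = gates)
}

# Bidirectional encoding of the real prefix; padded positions carry zero
# states. h_t is the concatenation of the forward and backward states at t.
bilstm_encode <- function(X, mask, lstm_f, lstm_b) {
  Treal <- sum(mask)
  if (Treal == 0L) stop("document has no real tokens", call. = FALSE)
  Xr <- X[seq_len(Treal), , drop = FALSE]
  fwd <- lstm_run(lstm_f, Xr)
  bwd <- lstm_run(lstm_b, Xr[Treal:1, , drop = FALSE])
  Hb <- bwd$h[Treal:1, , drop = FALSE]     # backward states in document order
  Hseq <- matrix(0, nrow(X), 2L * ncol(fwd$h))
  Hseq[seq_len(Treal), ] <- cbind(fwd$h, Hb)
  list(Hseq = Hseq, fwd = fwd, bwd = bwd, Treal = Treal)
}

# Sentence summary z_B: either the conventional concatenation of the two
# directional final states, or a per-coordinate max over real hidden states.
context_summary <- function(enc, method = "final") {
  Treal <- enc$Treal
  H <- ncol(enc$fwd$h)
  if (method == "final") {
    list(zB = c(enc$fwd$h[Treal, ], enc$bwd$h[Treal, ]), argmax = NULL)
  } else {
    Hr <- enc$Hseq[seq_len(Treal), , drop = FALSE]
    list(zB = apply(Hr, 2L, max), argmax = apply(Hr, 2L, which.max))
  }
}

# Word-level additive attention over real hidden states:
# u_t = tanh(W_c h_t + b_c), alpha = softmax(u_t . u_w), l_w = sum alpha_t h_t.
word_attend <- function(Hseq, Treal, wa) {
  Hr <- Hseq[seq_len(Treal), , drop = FALSE]
  U <- tanh(Hr %*% t(wa$W) + matrix(wa$b, Treal, length(wa$b), byrow = TRUE))
  s <- as.vector(U %*% wa$u)
  alpha <- softmax_stable(s)
  list(alpha = alpha, lw = as.vector(crossprod(Hr, alpha)), U = U, scores = s)
}

apply_act <- function(x, act) {
  switch(act, tanh = tanh(x), relu = pmax(x, 0), identity = x)
}

# Fusion MLP of the middle module: l_F = [l_r, l_w], p_F = act(W l_F + b).
fuse_middle <- function(lr, lw, par, act) {
  lF <- c(lr, lw)
  pre <- as.vector(par$W %*% lF) + par$b
  list(lF = lF, pre = pre, pF = apply_act(pre, act))
}

affine <- function(par, x) as.vector(par$W %*% x) + par$b

# Full forward pass on one encoded document. Returns the loss pieces and a
# cache sufficient for backprop. `ids` may carry trailing padding; documents
# shorter than the largest filter height are padded up to it.
forward_doc <- function(model, ids, train = FALSE) {
  ctl <- model$control; P <- model$params; vs <- model$vspec
  kmax <- max(ctl$filter_heights)
  ids <- as.integer(ids)
  if (length(ids) < kmax)
    ids <- c(ids, rep(model$vocab$pad_id, kmax - length(ids)))
  emb <- embed_doc(ids, P$emb, model$vocab$pad_id)
  X0 <- emb$X; mask <- emb$mask
  Treal <- sum(mask)
  if (Treal == 0L) stop("document contains only padding", call. = FALSE)
  if (!all(mask[seq_len(Treal)]))
    stop("padding must be trailing", call. = FALSE)

  drop_mask <- NULL
  if (train && ctl$dropout > 0) {
    keep <- 1 - ctl$dropout
    drop_mask <- matrix(stats::rbinom(length(X0), 1L, keep),
                        nrow(X0), ncol(X0)) / keep
    X <- X0 * drop_mask
  } else X <- X0

  # left branch: convolution maps, max pooling, phrase attention (or mean)
  maps <- lapply(seq_along(ctl$filter_heights), function(hi) {
    conv_feature_map(X, mask, P$conv[[hi]]$W, P$conv[[hi]]$b,
                     ctl$filter_heights[hi], ctl$conv_activation)
  })
  pool <- max_pool_concat(maps)
  zC <- pool$z
  if (vs$phrase_attn) {
    pattn <- lapply(seq_along(maps), function(hi) {
      pa <- P$pattn[[if (ctl$share_phrase_attn) 1L else hi]]
      phrase_attend(maps[[hi]], pa)
    })
    lr <- unlist(lapply(pattn, `[[`, "lr"), use.names = FALSE)
  } else {
    pattn <- NULL
    lr <- unlist(lapply(maps, function(m)
      masked_mean_rows(m$Z, which(m$valid))), use.names = FALSE)
  }

  # right branch: BiLSTM, sentence summary, word attention (or mean)
  enc <- bilstm_encode(X, mask, P$lstm_f, P$lstm_b)
  cs <- context_summary(enc, ctl$context_summary)
  zB <- cs$zB
  if (vs$word_attn) {
    wattn <- word_attend(enc$Hseq, enc$Treal, P$wattn)
    lw <- wattn$lw
  } else {
    wattn <- NULL
    lw <- masked_mean_rows(enc$Hseq, seq_len(enc$Treal))
  }

  # middle fusion and combination strategy
  if (vs$middle) {
    fus <- fuse_middle(lr, lw, P$fuse, ctl$mlp_activation)
    pF <- fus$pF
    if (vs$triple) {
      f <- affine(P$head_T, c(zC, zB, pF))
      sC <- sB <- sF <- NULL
    } else {
      sC <- affine(P$head_C, c(zC, pF))
      sB <- affine(P$head_B, c(zB, pF))
      sF <- affine(P$head_F, pF)
      w <- c(ctl$alpha, (1 - ctl$alpha) / 2, (1 - ctl$alpha) / 2)
      f <- w[1] * sC + w[2] * sB + w[3] * sF
    }
  } else {
    fus <- NULL; pF <- NULL
    sC <- affine(P$head_C, zC)
    sB <- affine(P$head_B, zB)
    sF <- NULL
    f <- ctl$alpha * sC + (1 - ctl$alpha) * sB
  }
  logp <- log_softmax_stable(f)

  list(ids = ids, mask = mask, Treal = Treal, X = X, drop_mask = drop_mask,
       maps = maps, pool = pool, pattn = pattn, lr = lr,
       enc = enc, cs = cs, wattn = wattn, lw = lw,
       fus = fus, pF = pF, sC = sC, sB = sB, sF = sF,
       f = f, logp = logp, p = exp(logp))
}

# Summed cross-entropy over a batch of (cache, label) pairs; the loss is a
# sum over documents (a mean is reported separately for logging).
doc_nll <- function(cache, y) -cache$logp[y]
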