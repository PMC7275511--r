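# Shared fixtures and independent scalar-loop oracles. The oracles evaluate
# the layer equations element by element with plain loops so that the
# vectorized implementations are checked against code that shares nothing
# with them.

tiny_control <- function(...) {
  fcnbla_control(embedding_dim = 4L, hidden_size = 3L,
                 filters_per_height = 2L, p_dim = 4L, dropout = 0, ...)
}

tiny_vocab <- function(n_tokens = 8L, seed = 42L) {
  toks <- letters[seq_len(n_tokens)]
  build_vocab(lapply(1:5, function(i) toks))
}

tiny_labels <- function(C = 3L) label_set(sprintf("cls%d", seq_len(C)))

tiny_model <- function(variant = "FCNBLA", control = tiny_control(),
                       C = 3L, seed = 5L, vocab = tiny_vocab()) {
  fcnbla:::new_model(vocab, tiny_labels(C), control, variant, seed = seed)
}

random_ids <- function(Tlen, vocab) {
  sample(3:vocab$size, Tlen, replace = TRUE)   # skip pad/unk
}

# --- oracles ---------------------------------------------------------------

# Narrow convolution: response of filter f at window i, one product at a time.
conv_loop <- function(X, W, b, k, relu = TRUE) {
  Tlen <- nrow(X); d <- ncol(X); j <- nrow(W)
  N <- Tlen - k + 1L
  Z <- matrix(0, N, j)
  for (i in seq_len(N)) for (f in seq_len(j)) {
    acc <- b[f]
    for (s in 0:(k - 1L)) for (m in seq_len(d))
      acc <- acc + W[f, s * d + m] * X[i + s, m]
    Z[i, f] <- if (relu) max(acc, 0) else acc
  }
  Z
}

# One LSTM direction, cell by cell and coordinate by coordinate.
lstm_loop <- function(par, Xr) {
  H <- length(par$b) / 4L
  Tn <- nrow(Xr)
  hs <- matrix(0, Tn, H)
  h <- rep(0, H); cc <- rep(0, H)
  sig <- function(x) 1 / (1 + exp(-x))
  for (t in seq_len(Tn)) {
    a <- as.vector(par$W %*% Xr[t, ]) + as.vector(par$U %*% h) + par$b
    hn <- rep(0, H); cn <- rep(0, H)
    for (m in seq_len(H)) {
      i_ <- sig(a[m]); f_ <- sig(a[H + m])
      g_ <- tanh(a[2 * H + m]); o_ <- sig(a[3 * H + m])
      cn[m] <- f_ * cc[m] + i_ * g_
      hn[m] <- o_ * tanh(cn[m])
    }
    h <- hn; cc <- cn
    hs[t, ] <- h
  }
  hs
}

# Additive attention evaluated row by row: v = tanh(W z + b), scores v.u,
# softmax, weighted sum.
attn_loop <- function(M, W, b, u) {
  n <- nrow(M)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    v <- tanh(as.vector(W %*% M[i, ]) + b)
    scores[i] <- sum(v * u)
  }
  e <- exp(scores - max(scores))
  w <- e / sum(e)
  out <- rep(0, ncol(M))
  for (i in seq_len(n)) out <- out + w[i] * M[i, ]
  list(weights = w, out = out)
}

# Central finite differences of the summed NLL w.r.t. all parameters.
numeric_grad <- function(model, batch, eps = 1e-5, idx = NULL) {
  theta0 <- fcnbla:::flatten_params(model$params)
  lossfun <- function(th) {
    model$params <- fcnbla:::unflatten_params(th, model$params)
    sum(vapply(batch, function(b)
      fcnbla:::doc_nll(fcnbla:::forward_doc(model, b$ids), b$y), 0))
  }
  if (is.null(idx)) idx <- seq_along(theta0)
  g <- numeric(length(theta0))
  for (i in idx) {
    tp <- theta0; tp[i] <- tp[i] + eps
    tm <- theta0; tm[i] <- tm[i] - eps
    g[i] <- (lossfun(tp) - lossfun(tm)) / (2 * eps)
  }
  g
}

analytic_grad <- function(model, batch) {
  g <- fcnbla:::zero_like(model$params)
  for (b in batch) {
    cache <- fcnbla:::forward_doc(model, b$ids)
    g <- fcnbla:::backward_doc(model, cache, b$y, g)
  }
  fcnbla:::flatten_params(g)
}

# Frozen pad-column indices of the embedding (excluded from comparison; the
# column is held at zero by design).
pad_col_idx <- function(model)
  (model$vocab$pad_id - 1L) * model$dims$d + seq_len(model$dims$d)

# Bag-of-words majority-signature classifier: assigns the class whose
# signature tokens occur most often; ties break toward higher prevalence
# (lower class index). Brute-force learnability oracle for the generator.
bow_signature_classify <- function(records, manifest, classes) {
  sig_sets <- lapply(classes, function(cl)
    c(unlist(manifest$signature_unigrams[[cl]]),
      unlist(manifest$signature_bigrams[[cl]])))
  vapply(records, function(r) {
    hits <- vapply(sig_sets, function(s) sum(r$tokens %in% s), 0)
    classes[which.max(hits)]
  }, character(1))
}

# A trivially separable micro-corpus: each class has one dominant token.
separable_corpus <- function(n_per_class = 10L, C = 2L, len = 6L, seed = 3L) {
  fcnbla:::with_seed(seed, {
    classes <- sprintf("k%d", seq_len(C))
    docs <- list()
    for (ci in seq_len(C)) for (i in seq_len(n_per_class)) {
      toks <- c(rep(sprintf("sig%d", ci), len - 2L),
                sample(c("bg1", "bg2"), 2L, replace = TRUE))
      docs[[length(docs) + 1L]] <- list(
        tokens = sample(toks), label = classes[ci],
        doc_id = sprintf("d%02d_%d", i, ci))
    }
    list(docs = docs[sample.int(length(docs))], labels = label_set(classes))
  })
}
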