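#' Model and training hyperparameters
#'
#' Defaults are the study settings: 300-dimensional embeddings initialised
#' uniformly on \eqn{[-\sqrt{3/d}, +\sqrt{3/d}]}, filter heights {2,3,4} with
#' 50 filters each, per-direction LSTM hidden size 200 (400-dimensional
#' sentence representation), fusion blend weight alpha = 0.3 with
#' beta = gamma = (1-alpha)/2, Adam with learning rate 0.001, dropout 0.2 on
#' the embedding outputs, batch size 16, early-stopping patience 20, at most
#' 100 epochs.
#'
#' @param embedding_dim Embedding dimension d.
#' @param filter_heights Integer vector of convolution filter heights k.
#' @param filters_per_height Filters j per height.
#' @param hidden_size Per-direction LSTM hidden size H.
#' @param p_dim Dimension of the fused representation p_F.
#' @param attn_dim_phrase Projection dimension of the phrase-attention MLP;
#'   \code{NULL} means equal to \code{filters_per_height}.
#' @param attn_dim_word Projection dimension of the word-attention MLP;
#'   \code{NULL} means equal to \code{2 * hidden_size}.
#' @param conv_activation \code{"relu"} (default) or \code{"identity"},
#'   applied to filter responses before pooling and phrase attention.
#' @param mlp_activation Activation of the fusion MLP: \code{"tanh"}
#'   (default), \code{"relu"} or \code{"identity"}.
#' @param context_summary How the context vector z_B is built:
#'   \code{"final"} (concatenation of the two directional final states,
#'   default) or \code{"maxpool"} (per-coordinate max over hidden states).
#' @param share_phrase_attn Share one set of phrase-attention parameters
#'   across filter heights (default \code{FALSE}: independent per height).
#' @param alpha Blend weight of the local head; the context and fusion heads
#'   each receive (1 - alpha) / 2.
#' @param learning_rate,batch_size,max_epochs,dropout,patience Training
#'   protocol (Adam).
#' @param grad_clip Optional global gradient-norm clip; \code{NULL} disables.
#' @param min_freq Minimum token frequency for the fitted vocabulary.
#' @return An object of class \code{"fcnbla_control"}.
#' @export
fcnbla_control <- function(embedding_dim = 300L,
                           filter_heights = c(2L, 3L, 4L),
                           filters_per_height = 50L,
                           hidden_size = 200L,
                           p_dim = 200L,
                           attn_dim_phrase = NULL,
                           attn_dim_word = NULL,
                           conv_activation = c("relu", "identity"),
                           mlp_activation = c("tanh", "relu", "identity"),
                           context_summary = c("final", "maxpool"),
                           share_phrase_attn = FALSE,
                           alpha = 0.3,
                           learning_rate = 0.001,
                           batch_size = 16L,
                           max_epochs = 100L,
                           dropout = 0.2,
                           patience = 20L,
                           grad_clip = NULL,
                           min_freq = 1L) {
  conv_activation <- match.arg(conv_activation)
  mlp_activation <- match.arg(mlp_activation)
  context_summary <- match.arg(context_summary)
  if (!(alpha >= 0 && alpha <= 1))
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (!(dropout >= 0 && dropout < 1))
    stop("dropout must lie in [0, 1)", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (patience < 1L || patience > max_epochs)
    stop("patience must lie in [1, max_epochs]", call. = FALSE)
  structure(list(
    embedding_dim = as.integer(embedding_dim),
    filter_heights = sort(as.integer(filter_heights)),
    filters_per_height = as.integer(filters_per_height),
    hidden_size = as.integer(hidden_size),
    p_dim = as.integer(p_dim),
    attn_dim_phrase = if (is.null(attn_dim_phrase)) NULL else as.integer(attn_dim_phrase),
    attn_dim_word = if (is.null(attn_dim_word)) NULL else as.integer(attn_dim_word),
    conv_activation = conv_activation,
    mlp_activation = mlp_activation,
    context_summary = context_summary,
    share_phrase_attn = isTRUE(share_phrase_attn),
    alpha = alpha,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    dropout = dropout,
    patience = as.integer(patience),
    grad_clip = grad_clip,
    min_freq = as.integer(min_freq)), class = "fcnbla_control")
}

#' Model variants
#'
#' \describe{
#'   \item{FCNBLA}{the full model: both attentions, MLP fusion, three-head
#'     pairwise combination.}
#'   \item{FNOA}{no attention: both attention outputs replaced by masked
#'     mean pooling (the uniform-weight limit of the attention softmax).}
#'   \item{FCNA}{phrase-level attention only; the word side is mean-pooled.}
#'   \item{FBLA}{word-level attention only; the phrase side is mean-pooled.}
#'   \item{CNBL}{the middle module removed entirely: no attention, no MLP
#'     fusion; the two branch summaries feed their heads directly and the
#'     blend is alpha * s_C + (1 - alpha) * s_B.}
#'   \item{TCNBLA}{triple concatenation: [z_C, z_B, p_F] through a single
#'     fully connected + softmax head instead of the pairwise heads.}
#' }
#'
#' @param name Variant name.
#' @return A list of structure flags (internal).
#' @keywords internal
variant_spec <- function(name) {
  name <- toupper(name)
  known <- c("FCNBLA", "FNOA", "FCNA", "FBLA", "CNBL", "TCNBLA")
  if (!name %in% known)
    stop("unknown variant '", name, "'; expected one of ",
         paste(known, collapse = ", "), call. = FALSE)
  list(name = name,
       phrase_attn = name %in% c("FCNBLA", "FCNA", "TCNBLA"),
       word_attn = name %in% c("FCNBLA", "FBLA", "TCNBLA"),
       middle = name != "CNBL",
       triple = name == "TCNBLA")
}

# LeCun-style uniform draw on [-sqrt(3/fan_in), +sqrt(3/fan_in)] -- the same
# rule the embedding initialisation states, applied with the layer's fan-in.
runif_fan <- function(nrow, ncol, fan_in = ncol) {
  b <- sqrt(3 / fan_in)
  matrix(stats::runif(nrow * ncol, -b, b), nrow, ncol)
}

orthogonal_matrix <- function(n) {
  qr_d <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_d)
  q * sign(diag(qr.R(qr_d)))  # fix sign ambiguity for determinism of scale
}

#' Initialise an embedding table
#'
#' Entries are uniform on \eqn{[-\sqrt{3/d}, +\sqrt{3/d}]}; the padding
#' column is all zeros and is excluded from gradient updates.
#'
#' @param vocab_size Vocabulary size |V| (>= 2).
#' @param d Embedding dimension.
#' @param pad_id Column index fixed at zero.
#' @param seed Optional seed (uses a private RNG stream when given).
#' @return A d x |V| matrix.
#' @export
init_embedding <- function(vocab_size, d, pad_id = 1L, seed = NULL) {
  stopifnot(vocab_size >= 2L, d >= 1L)
  draw <- function() {
    b <- sqrt(3 / d)
    E <- matrix(stats::runif(d * vocab_size, -b, b), d, vocab_size)
    E[, pad_id] <- 0
    E
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Full parameter set for a variant. Gate order in LSTM blocks: input, forget,
# cell, output; forget-gate bias starts at 1 for trainability.
init_params <- function(vocab_size, n_classes, control, vspec, pad_id = 1L) {
  d <- control$embedding_dim
  j <- control$filters_per_height
  H <- control$hidden_size
  heights <- control$filter_heights
  a_p <- if (is.null(control$attn_dim_phrase)) j else control$attn_dim_phrase
  a_w <- if (is.null(control$attn_dim_word)) 2L * H else control$attn_dim_word
  zc_dim <- length(heights) * j
  zb_dim <- 2L * H
  p_dim <- control$p_dim

  lstm_par <- function() {
    U <- do.call(rbind, replicate(4, orthogonal_matrix(H), simplify = FALSE))
    b <- rep(0, 4 * H); b[(H + 1):(2 * H)] <- 1
    list(W = runif_fan(4 * H, d), U = U, b = b)
  }
  attn_par <- function(a, din) {
    list(W = runif_fan(a, din), b = rep(0, a),
         u = stats::runif(a, -sqrt(3 / a), sqrt(3 / a)))
  }
  affine_par <- function(nout, nin)
    list(W = runif_fan(nout, nin), b = rep(0, nout))

  P <- list(emb = init_embedding(vocab_size, d, pad_id))
  P$conv <- lapply(heights, function(k) affine_par(j, k * d))
  P$lstm_f <- lstm_par()
  P$lstm_b <- lstm_par()
  if (vspec$phrase_attn) {
    n_attn <- if (control$share_phrase_attn) 1L else length(heights)
    P$pattn <- replicate(n_attn, attn_par(a_p, j), simplify = FALSE)
  }
  if (vspec$word_attn) P$wattn <- attn_par(a_w, zb_dim)
  if (vspec$middle) {
    P$fuse <- affine_par(p_dim, zc_dim + zb_dim)
    if (vspec$triple) {
      P$head_T <- affine_par(n_classes, zc_dim + zb_dim + p_dim)
    } else {
      P$head_F <- affine_par(n_classes, p_dim)
      P$head_C <- affine_par(n_classes, zc_dim + p_dim)
      P$head_B <- affine_par(n_classes, zb_dim + p_dim)
    }
  } else {
    P$head_C <- affine_par(n_classes, zc_dim)
    P$head_B <- affine_par(n_classes, zb_dim)
  }
  P
}

# Build an untrained model shell (used by the fitting function and by tests
# that poke the forward/backward pass directly).
new_model <- function(vocab, labels, control, variant = "FCNBLA", seed = NULL) {
  vspec <- variant_spec(variant)
  dims <- list(
    d = control$embedding_dim,
    j = control$filters_per_height,
    H = control$hidden_size,
    heights = control$filter_heights,
    a_p = if (is.null(control$attn_dim_phrase)) control$filters_per_height
          else control$attn_dim_phrase,
    a_w = if (is.null(control$attn_dim_word)) 2L * control$hidden_size
          else control$attn_dim_word,
    zc = length(control$filter_heights) * control$filters_per_height,
    zb = 2L * control$hidden_size,
    p = control$p_dim,
    C = labels$n_classes)
  params <- if (is.null(seed))
    init_params(vocab$size, labels$n_classes, control, vspec, vocab$pad_id)
  else with_seed(seed,
    init_params(vocab$size, labels$n_classes, control, vspec, vocab$pad_id))
  structure(list(params = params, dims = dims, control = control,
                 vspec = vspec, vocab = vocab, labels = labels),
            class = "fcnbla_model")
}

#' Number of trainable parameters of a model
#' @param model An \code{fcnbla_model} or fitted \code{fcnbla} object.
#' @return Integer count (the padding embedding column is not counted).
#' @export
n_parameters <- function(model) {
  p <- flatten_params(model$params)
  length(p) - model$dims$d  # pad column is frozen
}

# ---- parameter vector <-> nested list -------------------------------------

flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

# Write a flat vector back into the shapes of `template` (same traversal
# order as unlist on a nested list of numeric arrays).
unflatten_params <- function(flat, template) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  out <- walk(params_template <- template)
  stopifnot(pos == length(flat))
  out
}

# Elementwise map over two parameter structures of identical shape.
map2_params <- function(a, b, f) {
  if (is.list(a)) return(mapply(map2_params, a, b,
                                MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(a, b)
}

zero_like <- function(params) {
  if (is.list(params)) return(lapply(params, zero_like))
  params * 0
}
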