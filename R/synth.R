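# Class proportions of the ten-disease study corpus (training+validation+test
# counts per class, normalised), descending prevalence from ~30% to ~1.6%.
.default_props <- c(5645, 3947, 3300, 1451, 1076, 1069, 730, 657, 436, 290) / 18601
.default_classes <- c("diabetes", "hypertension", "COPD", "arrhythmia",
                      "asthma", "gastritis", "gastric_polyps", "gout",
                      "gastric_ulcers", "UTI")

# Run expr with a private RNG stream seeded by `seed`; the caller's RNG state
# is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Controlled rounding of the class x split allocation: per-class largest
# remainders first, then single-document moves (each kept within the
# floor/ceiling of the exact share, so per-class deviation stays < 1) until
# the split totals equal the largest-remainder apportionment of n itself.
stratified_split_counts <- function(counts, props = c(0.7, 0.1, 0.2)) {
  n <- sum(counts)
  exact <- outer(counts, props)
  part <- t(vapply(counts, function(nc) largest_remainder(nc, props),
                   integer(length(props))))
  target <- largest_remainder(n, props)
  repeat {
    delta <- colSums(part) - target
    if (all(delta == 0L)) break
    s_over <- which.max(delta)
    s_under <- which.min(delta)
    movable <- which(part[, s_over] - 1L >= floor(exact[, s_over]) &
                     part[, s_under] + 1L <= ceiling(exact[, s_under]))
    if (length(movable) == 0L) break   # cannot happen for consistent totals
    gain <- (part[movable, s_over] - exact[movable, s_over]) +
      (exact[movable, s_under] - part[movable, s_under])
    c_mv <- movable[which.max(gain)]
    part[c_mv, s_over] <- part[c_mv, s_over] - 1L
    part[c_mv, s_under] <- part[c_mv, s_under] + 1L
  }
  part
}

# Deterministic apportionment of n into round(n * p) by largest remainders;
# ties broken by lower index. Guarantees sum == n and |n_i - n p_i| < 1.
largest_remainder <- function(n, p) {
  exact <- n * p
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    frac <- exact - base
    extra <- order(frac, seq_along(p), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Configuration for the synthetic EMR-like corpus generator
#'
#' The generator emulates the statistical structure the classifier assumes:
#' a strongly class-imbalanced label distribution (defaults mirror the
#' ten-disease study corpus, from about 30\% down to 1.6\% prevalence),
#' variable document lengths, class-predictive signature words,
#' class-predictive two-word collocations emitted as adjacent pairs (so
#' phrase-level attention has signal distinct from unigram signal), and a
#' shared background vocabulary carrying no label information.
#'
#' @param n_classes Number of classes C.
#' @param class_proportions Simplex of length C; defaults to the ten-disease
#'   prevalences when \code{n_classes == 10}, else uniform.
#' @param class_names Optional class names; defaults to the ten disease names
#'   or \code{"class01"}, ...
#' @param n_docs Total number of documents.
#' @param doc_length_range Integer \code{c(L_min, L_max)}; lengths are drawn
#'   uniformly. \code{L_min} must be at least the largest filter height used
#'   downstream (4 by default).
#' @param signature_words_per_class Distinct signature unigrams per class.
#' @param signature_bigrams_per_class Distinct signature collocations per
#'   class; each is a dedicated ordered token pair.
#' @param p_sig Probability that a sampling step emits class signal rather
#'   than background, in (0, 1).
#' @param bigram_frac Given a signal step, probability it emits a collocation
#'   (two adjacent tokens) rather than a unigram.
#' @param background_vocab_size Number of shared background token types.
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @return An object of class \code{"fcnbla_synth_config"}.
#' @export
synth_config <- function(n_classes = 10L,
                         class_proportions = NULL,
                         class_names = NULL,
                         n_docs = 1000L,
                         doc_length_range = c(20L, 50L),
                         signature_words_per_class = 5L,
                         signature_bigrams_per_class = 3L,
                         p_sig = 0.7,
                         bigram_frac = 0.5,
                         background_vocab_size = 390L,
                         seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (is.null(class_proportions))
    class_proportions <- if (n_classes == 10L) .default_props
                         else rep(1 / n_classes, n_classes)
  if (length(class_proportions) != n_classes)
    stop("class_proportions must have length n_classes", call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions <= 0))
    stop("class_proportions must be a positive simplex", call. = FALSE)
  if (!(p_sig > 0 && p_sig < 1))
    stop("p_sig must lie strictly in (0, 1)", call. = FALSE)
  if (doc_length_range[1] < 4L)
    stop("L_min must be >= 4 (largest default filter height)", call. = FALSE)
  if (is.null(class_names))
    class_names <- if (n_classes == 10L) .default_classes
                   else sprintf("class%02d", seq_len(n_classes))
  structure(list(
    n_classes = n_classes, class_proportions = class_proportions,
    class_names = class_names, n_docs = as.integer(n_docs),
    doc_length_range = as.integer(doc_length_range),
    signature_words_per_class = as.integer(signature_words_per_class),
    signature_bigrams_per_class = as.integer(signature_bigrams_per_class),
    p_sig = p_sig, bigram_frac = bigram_frac,
    background_vocab_size = as.integer(background_vocab_size),
    seed = as.integer(seed)), class = "fcnbla_synth_config")
}

# Signature token inventory for a config: per class, unigram types and
# ordered bigram pairs; plus the shared background types.
synth_lexicon <- function(config) {
  cls <- seq_len(config$n_classes)
  uni <- lapply(cls, function(c)
    sprintf("c%02d_sig%d", c, seq_len(config$signature_words_per_class)))
  big <- lapply(cls, function(c)
    lapply(seq_len(config$signature_bigrams_per_class), function(b)
      c(sprintf("c%02d_bg%d_a", c, b), sprintf("c%02d_bg%d_b", c, b))))
  bg <- sprintf("w%04d", seq_len(config$background_vocab_size))
  list(unigrams = uni, bigrams = big, background = bg)
}

sample_doc_tokens <- function(len, cls, lex, config) {
  toks <- character(len)
  pos <- 1L
  nu <- config$signature_words_per_class
  nb <- config$signature_bigrams_per_class
  while (pos <= len) {
    if (stats::runif(1) < config$p_sig) {
      if (nb > 0L && pos < len && stats::runif(1) < config$bigram_frac) {
        pair <- lex$bigrams[[cls]][[sample.int(nb, 1L)]]
        toks[pos] <- pair[1]; toks[pos + 1L] <- pair[2]
        pos <- pos + 2L
        next
      }
      toks[pos] <- lex$unigrams[[cls]][[sample.int(nu, 1L)]]
    } else {
      toks[pos] <- lex$background[[sample.int(length(lex$background), 1L)]]
    }
    pos <- pos + 1L
  }
  toks
}

#' Generate a stratified synthetic labeled corpus
#'
#' Class counts follow \code{class_proportions} deterministically (largest
#' remainders), each class is split 70/10/20 into train/validation/test with
#' deviation at most one document, and document order within each split is a
#' seeded shuffle. Identical config and seed yield identical corpora.
#'
#' @param config A [synth_config()].
#' @param dir Optional directory; when given, \code{train.jsonl},
#'   \code{validation.jsonl}, \code{test.jsonl}, \code{labels.txt} and a
#'   \code{manifest.json} recording the config are written there.
#' @return A list with elements \code{train}, \code{validation}, \code{test}
#'   (record lists as in [read_records()]), \code{labels}
#'   (an \code{fcnbla_labels}), and \code{manifest}.
#' @export
generate_corpus <- function(config, dir = NULL) {
  stopifnot(inherits(config, "fcnbla_synth_config"))
  counts <- largest_remainder(config$n_docs, config$class_proportions)
  if (any(counts < 3L))
    stop("n_docs too small to stratify every class across 3 splits",
         call. = FALSE)
  lex <- synth_lexicon(config)
  labels <- label_set(config$class_names)

  parts <- stratified_split_counts(counts)
  res <- with_seed(config$seed, {
    splits <- list(train = list(), validation = list(), test = list())
    doc_no <- 0L
    for (cls in seq_len(config$n_classes)) {
      n_c <- counts[cls]
      part <- parts[cls, ]
      lens <- sample(seq(config$doc_length_range[1], config$doc_length_range[2]),
                     n_c, replace = TRUE)
      docs <- lapply(seq_len(n_c), function(i) {
        doc_no <<- doc_no + 1L
        list(tokens = sample_doc_tokens(lens[i], cls, lex, config),
             label = config$class_names[cls],
             doc_id = sprintf("synth-%06d", doc_no))
      })
      idx <- list(seq_len(part[1]),
                  seq_len(part[2]) + part[1],
                  seq_len(part[3]) + part[1] + part[2])
      for (s in 1:3)
        splits[[s]] <- c(splits[[s]], docs[idx[[s]]])
    }
    # shuffle within split so classes are interleaved
    for (s in 1:3) splits[[s]] <- splits[[s]][sample.int(length(splits[[s]]))]
    splits
  })

  manifest <- list(
    generator = "fcnbla::generate_corpus", version = 1L,
    config = unclass(config),
    class_counts = stats::setNames(as.list(counts), config$class_names),
    signature_unigrams = stats::setNames(lex$unigrams, config$class_names),
    signature_bigrams = stats::setNames(
      lapply(lex$bigrams, function(bs) lapply(bs, identity)),
      config$class_names))

  out <- list(train = res$train, validation = res$validation,
              test = res$test, labels = labels, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_records(out$train, file.path(dir, "train.jsonl"))
    write_records(out$validation, file.path(dir, "validation.jsonl"))
    write_records(out$test, file.path(dir, "test.jsonl"))
    write_label_set(labels, file.path(dir, "labels.txt"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Empirical per-class signal rate of a generated corpus
#'
#' Counts signal events per class — a signature unigram, or an adjacent
#' signature collocation pair counted once — over all sampling events, and
#' compares the empirical rate with the configured \code{p_sig}. Used to
#' verify the generator before model tests rely on it.
#'
#' @param corpus Output of [generate_corpus()] (or any of its split lists
#'   combined), with its manifest.
#' @return Data frame with one row per class: documents, sampling events,
#'   signal events and the empirical signal rate.
#' @export
corpus_separability_report <- function(corpus) {
  man <- corpus$manifest
  classes <- corpus$labels$classes
  docs <- c(corpus$train, corpus$validation, corpus$test)
  rows <- lapply(seq_along(classes), function(ci) {
    cl <- classes[ci]
    cdocs <- Filter(function(d) d$label == cl, docs)
    uni <- unlist(man$signature_unigrams[[cl]])
    big_a <- vapply(man$signature_bigrams[[cl]], `[`, character(1), 1L)
    n_events <- 0L; n_signal <- 0L
    for (d in cdocs) {
      is_a <- d$tokens %in% big_a
      n_pairs <- sum(is_a)
      n_uni <- sum(d$tokens %in% uni)
      n_events <- n_events + length(d$tokens) - n_pairs
      n_signal <- n_signal + n_uni + n_pairs
    }
    data.frame(class = cl, n_docs = length(cdocs), events = n_events,
               signal_events = n_signal,
               signal_rate = if (n_events > 0) n_signal / n_events else NA_real_)
  })
  do.call(rbind, rows)
}
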