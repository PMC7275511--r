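#' Train and compare ablation variants under identical data and seeds
#'
#' Trains each requested variant on the same corpus with the same seed(s)
#' and reports macro precision, macro recall, macro F-score and accuracy on
#' the corpus test split — one row per variant per seed.
#'
#' @param corpus A corpus as returned by [generate_corpus()] (elements
#'   \code{train}, \code{validation}, \code{test}, \code{labels}).
#' @param variants Character vector of variant names.
#' @param seeds Integer vector of training seeds.
#' @param control Shared [fcnbla_control()].
#' @param verbose Print a line per fit.
#' @return Data frame: \code{variant}, \code{seed}, \code{precision_macro},
#'   \code{recall_macro}, \code{f_score_macro}, \code{accuracy},
#'   \code{stopped_epoch}.
#' @export
run_ablation_suite <- function(corpus,
                               variants = c("FCNBLA", "FNOA", "FCNA",
                                            "FBLA", "CNBL", "TCNBLA"),
                               seeds = 1:5,
                               control = fcnbla_control(),
                               verbose = FALSE) {
  rows <- list()
  for (seed in seeds) {
    for (v in variants) {
      fit <- fcnbla(corpus$train, corpus$validation, labels = corpus$labels,
                    variant = v, control = control, seed = seed)
      rep_ <- evaluate_records(fit, corpus$test)
      if (verbose)
        message(sprintf("seed %d  %-7s macroF %.4f  acc %.4f",
                        seed, v, rep_$f_score_macro, rep_$accuracy))
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = seed,
        precision_macro = rep_$precision_macro,
        recall_macro = rep_$recall_macro,
        f_score_macro = rep_$f_score_macro,
        accuracy = rep_$accuracy,
        stopped_epoch = fit$stopped_epoch)
    }
  }
  do.call(rbind, rows)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint holds all parameters, the vocabulary, the label set (with
#' its order), the full control configuration and a format version, and
#' round-trips exactly.
#'
#' @param object A fitted [fcnbla()] model.
#' @param path Checkpoint file path.
#' @export
save_fcnbla <- function(object, path) {
  stopifnot(inherits(object, "fcnbla"))
  saveRDS(list(format = "fcnbla-checkpoint", version = 1L, object = object),
          path)
  invisible(path)
}

#' @rdname save_fcnbla
#' @export
load_fcnbla <- function(path) {
  if (!file.exists(path))
    stop("checkpoint not found: ", path, call. = FALSE)
  x <- readRDS(path)
  if (!identical(x$format, "fcnbla-checkpoint"))
    stop("not an fcnbla checkpoint: ", path, call. = FALSE)
  if (x$version > 1L)
    stop("checkpoint version ", x$version, " is newer than this package",
         call. = FALSE)
  x$object
}

#' Per-document attention weights for inspection
#'
#' Returns the phrase-level weights (one row per valid convolution window,
#' per filter height) and word-level weights (one row per token) of each
#' record, for export as a tabular text file.
#'
#' @param object A fitted [fcnbla()] model whose variant has at least one
#'   attention level.
#' @param records Records to inspect.
#' @return Data frame with columns \code{doc_id}, \code{level}
#'   (\code{"phrase"}/\code{"word"}), \code{height} (filter height, NA for
#'   word level), \code{position} (starting token index), \code{text} (the
#'   token or phrase), \code{weight}.
#' @export
attention_weights <- function(object, records) {
  if (!object$vspec$phrase_attn && !object$vspec$word_attn)
    stop("variant ", object$variant, " has no attention level", call. = FALSE)
  rows <- list()
  for (r in records) {
    ids <- tokens_to_ids(r$tokens, object$vocab)
    cache <- forward_doc(object, ids, train = FALSE)
    toks <- r$tokens
    if (object$vspec$phrase_attn) {
      for (hi in seq_along(cache$maps)) {
        k <- cache$maps[[hi]]$k
        att <- cache$pattn[[hi]]
        for (ii in seq_along(att$valid_idx)) {
          pos <- att$valid_idx[ii]
          rows[[length(rows) + 1L]] <- data.frame(
            doc_id = r$doc_id, level = "phrase", height = k, position = pos,
            text = paste(toks[pos:min(pos + k - 1L, length(toks))],
                         collapse = " "),
            weight = att$beta[pos])
        }
      }
    }
    if (object$vspec$word_attn) {
      for (t in seq_len(cache$Treal)) {
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = r$doc_id, level = "word", height = NA_integer_,
          position = t, text = toks[t], weight = cache$wattn$alpha[t])
      }
    }
  }
  do.call(rbind, rows)
}

#' @rdname attention_weights
#' @param weights Data frame from [attention_weights()].
#' @param path Output TSV path.
#' @export
write_attention_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
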