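#' Whitespace tokenizer
#'
#' Default tokenizer: splits on runs of whitespace. Any function with the
#' signature \code{function(text) character()} can be supplied wherever a
#' tokenizer is accepted (e.g. a Chinese word segmenter); the package itself
#' assumes nothing about the language beyond "documents are token sequences".
#'
#' @param text A single character string.
#' @return Character vector of tokens; \code{character(0)} for empty input.
#' @export
#' @examples
#' tokenize_whitespace("chest pain")
tokenize_whitespace <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  strsplit(trimws(text), "\\s+")[[1]]
}

#' Build a vocabulary from a tokenized corpus
#'
#' Tokens occurring fewer than \code{min_freq} times are dropped (they will
#' map to the unknown id). The special tokens \code{"<pad>"} and
#' \code{"<unk>"} are always present, at ids 1 and 2.
#'
#' @param corpus A list of character vectors (tokenized documents).
#' @param min_freq Minimum corpus frequency for a token to receive its own id.
#' @return An object of class \code{"fcnbla_vocab"}: a list with
#'   \code{token_to_id} (named integer vector), \code{id_to_token},
#'   \code{pad_id}, \code{unk_id} and \code{size}.
#' @export
build_vocab <- function(corpus, min_freq = 1L) {
  if (length(corpus) == 0L)
    stop("cannot build a vocabulary from an empty corpus", call. = FALSE)
  stopifnot(min_freq >= 1L)
  tokens <- unlist(corpus, use.names = FALSE)
  freq <- table(tokens)
  keep <- sort(names(freq)[freq >= min_freq])
  keep <- setdiff(keep, c("<pad>", "<unk>"))
  id_to_token <- c("<pad>", "<unk>", keep)
  token_to_id <- stats::setNames(seq_along(id_to_token), id_to_token)
  structure(
    list(token_to_id = token_to_id, id_to_token = id_to_token,
         pad_id = 1L, unk_id = 2L, size = length(id_to_token)),
    class = "fcnbla_vocab")
}

#' @export
print.fcnbla_vocab <- function(x, ...) {
  cat("Vocabulary:", x$size, "tokens (incl. <pad>, <unk>)\n")
  invisible(x)
}

#' Map raw tokens to vocabulary ids
#'
#' Tokens absent from the vocabulary map to the unknown id; this is the only
#' out-of-vocabulary policy, applied identically at training and prediction
#' time.
#'
#' @param tokens Character vector of raw tokens.
#' @param vocab A vocabulary from [build_vocab()].
#' @return Integer vector of token ids.
#' @export
tokens_to_ids <- function(tokens, vocab) {
  ids <- unname(vocab$token_to_id[tokens])
  ids[is.na(ids)] <- vocab$unk_id
  as.integer(ids)
}

#' Define an ordered label set
#'
#' The class order is significant: it fixes the class indices used everywhere
#' (loss, confusion matrix, reports) and is persisted inside fitted models.
#'
#' @param classes Character vector of distinct class names, C >= 2.
#' @return Object of class \code{"fcnbla_labels"}.
#' @export
label_set <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) < 2L || anyDuplicated(classes))
    stop("a label set needs >= 2 distinct class names", call. = FALSE)
  structure(list(classes = classes,
                 index = stats::setNames(seq_along(classes), classes),
                 n_classes = length(classes)),
            class = "fcnbla_labels")
}

#' @export
print.fcnbla_labels <- function(x, ...) {
  cat("Label set (", x$n_classes, " classes): ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a label set file (one class name per line, order significant)
#' @param path File path.
#' @return [read_label_set()] returns an \code{fcnbla_labels} object.
#' @export
read_label_set <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  label_set(lines[nzchar(lines)])
}

#' @rdname read_label_set
#' @param labels An \code{fcnbla_labels} object.
#' @export
write_label_set <- function(labels, path) {
  writeLines(labels$classes, path, useBytes = TRUE)
  invisible(path)
}

#' Read labeled records from a line-delimited JSON file
#'
#' One JSON object per line with fields \code{tokens} (array of strings) or
#' \code{text} (string, split with \code{tokenizer}), \code{label} (string)
#' and optional \code{doc_id}.
#'
#' @param path Record file path.
#' @param tokenizer Function used when a record carries \code{text} rather
#'   than \code{tokens}; defaults to [tokenize_whitespace()].
#' @return List of records, each a list with \code{tokens} (character),
#'   \code{label} (character scalar) and \code{doc_id}.
#' @export
read_records <- function(path, tokenizer = tokenize_whitespace) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("line %d: malformed record (%s)",
                                   i, conditionMessage(e)), call. = FALSE))
    if (is.null(rec$label) || !nzchar(rec$label))
      stop(sprintf("line %d: record is missing a 'label' field", i),
           call. = FALSE)
    toks <- if (!is.null(rec$tokens)) as.character(rec$tokens)
            else if (!is.null(rec$text)) tokenizer(rec$text)
            else stop(sprintf("line %d: record has neither 'tokens' nor 'text'", i),
                      call. = FALSE)
    out[[i]] <- list(tokens = toks, label = as.character(rec$label),
                     doc_id = if (is.null(rec$doc_id)) sprintf("doc%06d", i)
                              else as.character(rec$doc_id))
  }
  out
}

#' @rdname read_records
#' @param records List of records as returned by [read_records()].
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(tokens = r$tokens, label = jsonlite::unbox(r$label),
                          doc_id = jsonlite::unbox(r$doc_id)))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Encode raw-token records against a vocabulary and label set
#'
#' @param records List of records (see [read_records()]).
#' @param vocab Vocabulary from [build_vocab()].
#' @param labels Label set from [label_set()].
#' @return List of encoded documents: \code{ids} (integer token ids),
#'   \code{y} (class index), \code{doc_id}.
#' @export
encode_records <- function(records, vocab, labels) {
  lapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (length(r$tokens) == 0L)
      stop(sprintf("record %d (%s) is empty", i, r$doc_id), call. = FALSE)
    y <- labels$index[r$label]
    if (is.na(y))
      stop(sprintf("record %d (%s): unknown class name '%s'",
                   i, r$doc_id, r$label), call. = FALSE)
    list(ids = tokens_to_ids(r$tokens, vocab), y = unname(y),
         doc_id = r$doc_id)
  })
}
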