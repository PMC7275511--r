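#' Loader for a structured clinical-record corpus (user-supplied)
#'
#' Reads a line-delimited JSON file in which every record is an object whose
#' \code{label_item} field carries the diagnosis (the class label) and whose
#' remaining fields are free-text items describing the patient (chief
#' complaint, vital signs, current medical history, ...). The item texts are
#' concatenated in a fixed, sorted key order into a single document, then
#' tokenized. Records whose every non-label item is missing or empty carry
#' no predictive text and are dropped — the loader reports how many.
#'
#' The corpus itself is not shipped and is never downloaded by the package;
#' the user supplies the file.
#'
#' @param path Path to a line-delimited JSON file, one record per line.
#' @param label_item Name of the field holding the diagnosis label.
#' @param tokenizer Tokenizer applied to the concatenated item text; for
#'   unsegmented Chinese text supply a segmenter (see
#'   [tokenize_whitespace()] for the contract).
#' @return A list with \code{records} (as in [read_records()]) and
#'   \code{n_dropped}, the number of label-only records removed.
#' @export
load_structured_records <- function(path, label_item = "initial_diagnosis",
                                    tokenizer = tokenize_whitespace) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  records <- list()
  n_dropped <- 0L
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
    if (is.null(rec[[label_item]]) || !nzchar(rec[[label_item]]))
      stop(sprintf("line %d: missing '%s' field", i, label_item),
           call. = FALSE)
    items <- rec[setdiff(names(rec), label_item)]
    items <- vapply(items, function(x)
      if (is.null(x) || length(x) == 0L) "" else as.character(x)[1],
      character(1))
    items <- items[nzchar(trimws(items))]
    if (length(items) == 0L) {        # label-only record: no text to learn from
      n_dropped <- n_dropped + 1L
      next
    }
    text <- paste(items[sort(names(items))], collapse = " ")
    records[[length(records) + 1L]] <-
      list(tokens = tokenizer(text), label = as.character(rec[[label_item]]),
           doc_id = sprintf("rec%06d", i))
  }
  list(records = records, n_dropped = n_dropped)
}
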