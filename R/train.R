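# Adam on the flattened parameter vector (beta1 = 0.9, beta2 = 0.999,
# eps = 1e-8, bias-corrected).
adam_step <- function(theta, grad, state, lr) {
  state$t <- state$t + 1L
  state$m <- 0.9 * state$m + 0.1 * grad
  state$v <- 0.999 * state$v + 0.001 * grad^2
  mhat <- state$m / (1 - 0.9^state$t)
  vhat <- state$v / (1 - 0.999^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + 1e-8), state = state)
}

#' Fit a dual-branch CNN/BiLSTM attention classifier
#'
#' Trains the full model or one of its ablation variants on tokenized,
#' labeled records with Adam on shuffled mini-batches, dropout on the
#' embedding outputs, and early stopping on the validation loss (the best
#' checkpoint is restored). The loss is the summed cross-entropy over each
#' batch; per-document means are logged.
#'
#' @param train List of records (see [read_records()]): each a list with
#'   \code{tokens} (character vector), \code{label}, \code{doc_id}.
#' @param validation Optional validation records. When omitted, no early
#'   stopping is applied and training runs for \code{max_epochs}.
#' @param labels An [label_set()]; defaults to the sorted unique training
#'   labels. The declared order fixes class indices and is persisted.
#' @param variant One of \code{"FCNBLA"}, \code{"FNOA"}, \code{"FCNA"},
#'   \code{"FBLA"}, \code{"CNBL"}, \code{"TCNBLA"} (see [variant_spec()]).
#' @param control Hyperparameters from [fcnbla_control()].
#' @param vocab Optional prebuilt [build_vocab()] vocabulary; defaults to one
#'   built from \code{train} at \code{control$min_freq}.
#' @param seed Integer seed governing initialisation, batch shuffling and
#'   dropout; identical seeds give identical fits.
#' @param verbose Print one line per epoch.
#' @return An object of class \code{"fcnbla"} with the best parameters, the
#'   vocabulary, the label set, the control settings and a per-epoch
#'   \code{history} data frame (training loss, validation loss, validation
#'   macro F-score).
#' @seealso [predict.fcnbla()], [evaluation_report()], [generate_corpus()]
#' @export
#' @examples
#' corp <- generate_corpus(synth_config(n_classes = 3, n_docs = 60,
#'                                      doc_length_range = c(8L, 14L),
#'                                      background_vocab_size = 30L, seed = 7))
#' ctl <- fcnbla_control(embedding_dim = 8L, hidden_size = 6L,
#'                       filters_per_height = 4L, p_dim = 8L, max_epochs = 2L,
#'                       patience = 2L)
#' fit <- fcnbla(corp$train, corp$validation, labels = corp$labels,
#'               control = ctl, seed = 1)
#' predict(fit, corp$test[1:2], type = "class")
fcnbla <- function(train, validation = NULL, labels = NULL,
                   variant = "FCNBLA", control = fcnbla_control(),
                   vocab = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(control, "fcnbla_control"))
  if (length(train) == 0L) stop("empty training set", call. = FALSE)
  if (!is.null(validation) && length(validation) == 0L)
    stop("validation set is empty; omit it instead", call. = FALSE)
  if (is.null(labels))
    labels <- label_set(sort(unique(vapply(train, `[[`, character(1), "label"))))
  if (is.null(vocab))
    vocab <- build_vocab(lapply(train, `[[`, "tokens"), control$min_freq)
  tr <- encode_records(train, vocab, labels)
  va <- if (is.null(validation)) NULL else encode_records(validation, vocab, labels)

  fit <- with_seed(seed, {
    model <- new_model(vocab, labels, control, variant)
    theta <- flatten_params(model$params)
    st <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
    pad_idx <- (vocab$pad_id - 1L) * model$dims$d + seq_len(model$dims$d)
    n <- length(tr)
    best <- list(loss = Inf, theta = theta, epoch = 0L)
    bad_epochs <- 0L
    hist <- list()
    stopped <- control$max_epochs
    for (epoch in seq_len(control$max_epochs)) {
      perm <- sample.int(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = control$batch_size)) {
        idx <- perm[start:min(start + control$batch_size - 1L, n)]
        g <- zero_like(model$params)
        for (i in idx) {
          cache <- forward_doc(model, tr[[i]]$ids, train = TRUE)
          epoch_loss <- epoch_loss + doc_nll(cache, tr[[i]]$y)
          g <- backward_doc(model, cache, tr[[i]]$y, g)
        }
        gflat <- flatten_params(g)
        gflat[pad_idx] <- 0
        if (!is.null(control$grad_clip)) {
          nrm <- sqrt(sum(gflat^2))
          if (nrm > control$grad_clip) gflat <- gflat * control$grad_clip / nrm
        }
        upd <- adam_step(theta, gflat, st, control$learning_rate)
        theta <- upd$theta; st <- upd$state
        model$params <- unflatten_params(theta, model$params)
      }
      train_loss <- epoch_loss / n
      if (!is.null(va)) {
        ev <- eval_split(model, va)
        val_loss <- ev$loss; val_f <- ev$macro_f
        if (val_loss < best$loss - 1e-12) {
          best <- list(loss = val_loss, theta = theta, epoch = epoch)
          bad_epochs <- 0L
        } else bad_epochs <- bad_epochs + 1L
      } else {
        val_loss <- NA_real_; val_f <- NA_real_
        best <- list(loss = train_loss, theta = theta, epoch = epoch)
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss, val_macro_f = val_f)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  macroF %.4f",
                        epoch, train_loss, val_loss, val_f))
      if (!is.null(va) && bad_epochs >= control$patience) {
        stopped <- epoch
        break
      }
      stopped <- epoch
    }
    model$params <- unflatten_params(best$theta, model$params)
    list(model = model, history = do.call(rbind, hist),
         best_epoch = best$epoch, best_val_loss = best$loss,
         stopped_epoch = stopped)
  })

  out <- fit$model
  out$variant <- out$vspec$name
  out$history <- fit$history
  out$best_epoch <- fit$best_epoch
  out$best_val_loss <- fit$best_val_loss
  out$stopped_epoch <- fit$stopped_epoch
  out$seed <- as.integer(seed)
  out$n_train <- length(tr)
  out$n_validation <- length(va)
  out$call <- match.call()
  class(out) <- c("fcnbla", "fcnbla_model")
  out
}

# Mean per-document NLL and macro-F of a model on an encoded split.
eval_split <- function(model, docs) {
  n <- length(docs)
  loss <- 0
  pred <- integer(n)
  truth <- integer(n)
  for (i in seq_len(n)) {
    cache <- forward_doc(model, docs[[i]]$ids, train = FALSE)
    loss <- loss + doc_nll(cache, docs[[i]]$y)
    pred[i] <- which.max(cache$p)
    truth[i] <- docs[[i]]$y
  }
  rep_ <- evaluation_report(confusion_counts(truth, pred, model$labels))
  list(loss = loss / n, macro_f = rep_$f_score_macro,
       accuracy = rep_$accuracy)
}

prepare_newdata <- function(object, newdata, tokenizer = tokenize_whitespace) {
  if (is.character(newdata))
    newdata <- lapply(seq_along(newdata), function(i)
      list(tokens = tokenizer(newdata[i]), label = NA_character_,
           doc_id = sprintf("new%04d", i)))
  lapply(newdata, function(r) {
    if (length(r$tokens) == 0L) stop("empty document", call. = FALSE)
    list(ids = tokens_to_ids(r$tokens, object$vocab), doc_id = r$doc_id)
  })
}

#' Predict disease classes for new records
#'
#' Deterministic (dropout is inactive); out-of-vocabulary tokens map to the
#' unknown id. Ties in the probability vector break toward the lowest class
#' index.
#'
#' @param object A fitted [fcnbla()] model.
#' @param newdata List of records (as from [read_records()]) or a character
#'   vector of raw texts (tokenized with the whitespace tokenizer).
#' @param type \code{"class"} (factor of predicted classes), \code{"prob"}
#'   (n x C probability matrix), \code{"score"} (pre-softmax blended scores
#'   f), or \code{"rank"} (n x C matrix of class names, most probable
#'   first).
#' @param ... Unused.
#' @return See \code{type}.
#' @export
predict.fcnbla <- function(object, newdata,
                           type = c("class", "prob", "score", "rank"), ...) {
  type <- match.arg(type)
  docs <- prepare_newdata(object, newdata)
  C <- object$labels$n_classes
  probs <- matrix(NA_real_, length(docs), C,
                  dimnames = list(vapply(docs, `[[`, character(1), "doc_id"),
                                  object$labels$classes))
  scores <- probs
  for (i in seq_along(docs)) {
    cache <- forward_doc(object, docs[[i]]$ids, train = FALSE)
    probs[i, ] <- cache$p
    scores[i, ] <- cache$f
  }
  switch(type,
    prob = probs,
    score = scores,
    class = factor(object$labels$classes[max.col(probs, ties.method = "first")],
                   levels = object$labels$classes),
    rank = t(apply(probs, 1L, function(p)
      object$labels$classes[order(p, decreasing = TRUE)])))
}

#' @export
print.fcnbla <- function(x, ...) {
  cat("Dual-branch CNN/BiLSTM attention classifier (variant ",
      x$variant, ")\n", sep = "")
  cat("  classes:   ", x$labels$n_classes, " (",
      paste(utils::head(x$labels$classes, 4), collapse = ", "),
      if (x$labels$n_classes > 4) ", ..." else "", ")\n", sep = "")
  cat("  vocabulary:", x$vocab$size, "tokens\n")
  cat("  parameters:", n_parameters(x), "\n")
  cat("  trained:   ", x$stopped_epoch, " epochs (best at ",
      x$best_epoch, ", val loss ",
      formatC(x$best_val_loss, digits = 4, format = "f"), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.fcnbla <- function(object, ...) {
  structure(list(fit = object), class = "summary.fcnbla")
}

#' @export
print.summary.fcnbla <- function(x, ...) {
  f <- x$fit
  print(f)
  d <- f$dims
  cat("\nArchitecture\n")
  cat(sprintf("  embedding d = %d; filter heights {%s} x %d filters -> z_C dim %d\n",
              d$d, paste(d$heights, collapse = ","), d$j, d$zc))
  cat(sprintf("  BiLSTM hidden %d per direction -> z_B dim %d; fusion p_F dim %d\n",
              d$H, d$zb, d$p))
  cat(sprintf("  blend alpha = %.2f (context and fusion heads %.2f each)\n",
              f$control$alpha, (1 - f$control$alpha) / 2))
  if (!is.null(f$history)) {
    cat("\nTraining history (last epochs)\n")
    print(utils::tail(f$history, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.fcnbla <- function(object, flat = FALSE, ...) {
  if (flat) flatten_params(object$params) else object$params
}

#' @export
plot.fcnbla <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("no training history to plot", call. = FALSE)
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "mean cross-entropy", ylim = ylim, ...)
  if (any(!is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2, lwd = 2)
  graphics::abline(v = x$best_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1:2, lwd = 2,
                   bty = "n")
  invisible(x)
}
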