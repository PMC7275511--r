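small_train_control <- function(...)
  fcnbla_control(embedding_dim = 8L, hidden_size = 6L,
                 filters_per_height = 4L, p_dim = 8L, ...)

test_that("the model overfits a trivially separable 20-document corpus", {
  corp <- separable_corpus(n_per_class = 10L, C = 2L)
  ctl <- small_train_control(max_epochs = 40L, patience = 40L,
                             batch_size = 4L)
  fit <- fcnbla(corp$docs, labels = corp$labels, control = ctl, seed = 2)
  pred <- predict(fit, corp$docs, type = "class")
  truth <- vapply(corp$docs, `[[`, character(1), "label")
  expect_equal(mean(as.character(pred) == truth), 1)
})

test_that("fits are reproducible from the seed", {
  corp <- separable_corpus()
  ctl <- small_train_control(max_epochs = 3L, patience = 3L)
  f1 <- fcnbla(corp$docs[1:12], corp$docs[13:20], labels = corp$labels,
               control = ctl, seed = 7)
  f2 <- fcnbla(corp$docs[1:12], corp$docs[13:20], labels = corp$labels,
               control = ctl, seed = 7)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1, flat = TRUE), coef(f2, flat = TRUE))
})

test_that("invalid training configurations are rejected", {
  expect_error(fcnbla_control(patience = 0L), "patience")
  expect_error(fcnbla_control(dropout = 1), "dropout")
  expect_error(fcnbla_control(batch_size = 0L), "batch_size")
  corp <- separable_corpus()
  expect_error(fcnbla(list(), labels = corp$labels), "empty")
  expect_error(fcnbla(corp$docs, validation = list(), labels = corp$labels),
               "validation")
})

test_that("early stopping restores the best validation checkpoint", {
  corp <- separable_corpus(n_per_class = 8L)
  ctl <- small_train_control(max_epochs = 10L, patience = 2L)
  fit <- fcnbla(corp$docs[1:10], corp$docs[11:16], labels = corp$labels,
                control = ctl, seed = 4)
  h <- fit$history
  expect_equal(fit$best_epoch, h$epoch[which.min(h$val_loss)])
  expect_equal(fit$best_val_loss, min(h$val_loss))
  expect_lte(fit$stopped_epoch, ctl$max_epochs)
})

test_that("prediction is deterministic, rank-consistent and batch-invariant", {
  corp <- separable_corpus()
  ctl <- small_train_control(max_epochs = 2L, patience = 2L)
  fit <- fcnbla(corp$docs, labels = corp$labels, control = ctl, seed = 9)
  docs <- corp$docs[1:5]
  p_batch <- predict(fit, docs, type = "prob")
  # one-by-one equals batched
  for (i in seq_along(docs))
    expect_equal(predict(fit, docs[i], type = "prob")[1, ], p_batch[i, ],
                 tolerance = 1e-6)
  # duplicated document, identical prediction; dropout is off at eval
  expect_equal(p_batch[1, ], predict(fit, docs[1], type = "prob")[1, ])
  # ranks are the descending argsort of the probabilities
  rk <- predict(fit, docs, type = "rank")
  for (i in seq_along(docs))
    expect_equal(rk[i, ], fit$labels$classes[order(p_batch[i, ],
                                                   decreasing = TRUE)])
  # raw text input goes through the tokenizer
  p_text <- predict(fit, "sig1 bg1 sig1 sig1 bg2 sig1", type = "class")
  expect_s3_class(p_text, "factor")
  # unseen tokens fall back to <unk> rather than failing
  expect_no_error(predict(fit, "never seen tokens at all", type = "prob"))
})

test_that("checkpoints round-trip the full model", {
  corp <- separable_corpus()
  ctl <- small_train_control(max_epochs = 2L, patience = 2L)
  fit <- fcnbla(corp$docs, labels = corp$labels, control = ctl, seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_fcnbla(fit, path)
  back <- load_fcnbla(path)
  expect_identical(coef(back, flat = TRUE), coef(fit, flat = TRUE))
  expect_identical(back$labels$classes, fit$labels$classes)
  expect_equal(predict(back, corp$docs[1:3], type = "prob"),
               predict(fit, corp$docs[1:3], type = "prob"))
  expect_error(load_fcnbla(withr::local_tempfile(fileext = ".rds")))
})

test_that("attention weights export one row per window and per token", {
  corp <- separable_corpus()
  ctl <- small_train_control(max_epochs = 1L, patience = 1L)
  fit <- fcnbla(corp$docs, labels = corp$labels, control = ctl, seed = 9)
  doc <- corp$docs[1]
  aw <- attention_weights(fit, doc)
  Tlen <- length(doc[[1]]$tokens)
  word <- aw[aw$level == "word", ]
  expect_equal(nrow(word), Tlen)
  expect_equal(sum(word$weight), 1, tolerance = 1e-6)
  for (k in fit$control$filter_heights) {
    ph <- aw[aw$level == "phrase" & aw$height == k, ]
    expect_equal(nrow(ph), Tlen - k + 1L)
    expect_equal(sum(ph$weight), 1, tolerance = 1e-6)
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  write_attention_weights(aw, path)
  expect_equal(nrow(utils::read.delim(path)), nrow(aw))
  # a no-attention variant has nothing to export
  noa <- fcnbla(corp$docs, labels = corp$labels, control = ctl,
                variant = "FNOA", seed = 9)
  expect_error(attention_weights(noa, doc), "no attention")
})

test_that("structured-record loader drops label-only records and reports", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"initial_diagnosis":"asthma","chief_complaint":"wheeze cough","history":""}',
    '{"initial_diagnosis":"gout","chief_complaint":"","history":""}',
    '{"initial_diagnosis":"asthma","history":"night cough"}'
  ), path)
  out <- load_structured_records(path)
  expect_equal(out$n_dropped, 1L)
  expect_length(out$records, 2L)
  expect_equal(out$records[[1]]$tokens, c("wheeze", "cough"))
  expect_equal(vapply(out$records, `[[`, character(1), "label"),
               c("asthma", "asthma"))
  writeLines('{"chief_complaint":"x"}', path)
  expect_error(load_structured_records(path), "missing")
})
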