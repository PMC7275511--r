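test_that("balanced two-class corpus gets exactly equal class counts", {
  corp <- generate_corpus(synth_config(n_classes = 2L,
                                       class_proportions = c(0.5, 0.5),
                                       n_docs = 100L,
                                       doc_length_range = c(6L, 10L),
                                       background_vocab_size = 30L, seed = 9))
  lab <- vapply(c(corp$train, corp$validation, corp$test), `[[`,
                character(1), "label")
  expect_equal(as.integer(table(lab)), c(50L, 50L))
})

test_that("default ten-class corpus splits exactly 700/100/200, stratified", {
  corp <- generate_corpus(synth_config(seed = 11))
  expect_length(corp$train, 700L)
  expect_length(corp$validation, 100L)
  expect_length(corp$test, 200L)
  all_lab <- vapply(c(corp$train, corp$validation, corp$test), `[[`,
                    character(1), "label")
  tot <- table(factor(all_lab, levels = corp$labels$classes))
  for (s in c("train", "validation", "test")) {
    p <- c(train = 0.7, validation = 0.1, test = 0.2)[[s]]
    tab <- table(factor(vapply(corp[[s]], `[[`, character(1), "label"),
                        levels = corp$labels$classes))
    expect_true(all(abs(tab - tot * p) < 1))   # per-class deviation < 1 doc
  }
  # prevalence spans the imbalanced range (about 30% down to about 1.6%)
  props <- sort(as.numeric(tot) / 1000, decreasing = TRUE)
  expect_gt(props[1], 0.28)
  expect_lt(props[10], 0.025)
})

test_that("identical config and seed reproduce the corpus byte for byte", {
  cfg <- synth_config(n_classes = 5L, n_docs = 200L, p_sig = 0.9,
                      doc_length_range = c(8L, 12L),
                      background_vocab_size = 50L, seed = 21)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("generator vocabulary matches the configured type inventory", {
  # 10 classes x 5 signature words + 10 x 3 x 2 collocation tokens + 390
  # background types = 500 emitted types; plus <pad>, <unk> = 502
  corp <- generate_corpus(synth_config(seed = 11))
  v <- build_vocab(lapply(c(corp$train, corp$validation, corp$test),
                          `[[`, "tokens"), min_freq = 1L)
  expect_equal(v$size, 502L)
})

test_that("empirical signal rate tracks p_sig", {
  mk <- function(p) generate_corpus(synth_config(
    n_classes = 3L, n_docs = 300L, p_sig = p,
    doc_length_range = c(20L, 40L), background_vocab_size = 60L, seed = 33))
  rep_mid <- corpus_separability_report(mk(0.5))
  expect_true(all(rep_mid$signal_rate > 0.47 & rep_mid$signal_rate < 0.53))
  rep_hi <- corpus_separability_report(mk(0.98))
  expect_true(all(rep_hi$signal_rate > 0.95))
  rep_lo <- corpus_separability_report(mk(0.02))
  expect_true(all(rep_lo$signal_rate < 0.05))
})

test_that("a bag-of-words signature oracle solves the default corpus", {
  corp <- generate_corpus(synth_config(seed = 11))   # p_sig = 0.7, 5 words
  pred <- bow_signature_classify(corp$test, corp$manifest,
                                 corp$labels$classes)
  truth <- vapply(corp$test, `[[`, character(1), "label")
  expect_gte(mean(pred == truth), 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(class_proportions = c(0.6, 0.6), n_classes = 2L),
               "simplex")
  expect_error(synth_config(p_sig = 0), "p_sig")
  expect_error(synth_config(doc_length_range = c(2L, 10L)), "L_min")
  expect_error(generate_corpus(synth_config(n_classes = 10L, n_docs = 20L)),
               "too small")
})

test_that("written corpus directory round-trips through the readers", {
  dir <- withr::local_tempdir()
  corp <- generate_corpus(synth_config(n_classes = 3L, n_docs = 60L,
                                       doc_length_range = c(6L, 9L),
                                       background_vocab_size = 20L,
                                       seed = 4), dir = dir)
  expect_equal(read_records(file.path(dir, "train.jsonl")), corp$train)
  expect_equal(read_label_set(file.path(dir, "labels.txt"))$classes,
               corp$labels$classes)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$config$seed, 4L)
})
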