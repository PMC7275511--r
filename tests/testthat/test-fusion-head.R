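test_that("zero fusion weights give p_F = act(0) and s_F = 0", {
  par <- list(W = matrix(0, 4, 6), b = rep(0, 4))
  out <- fcnbla:::fuse_middle(rep(1, 2), rep(1, 4), par, "tanh")
  expect_equal(out$pF, rep(0, 4))
  head_F <- list(W = matrix(0, 3, 4), b = rep(0, 3))
  expect_equal(fcnbla:::affine(head_F, out$pF), rep(0, 3))
})

test_that("fused input dimension is dim(l_r) + dim(l_w); 550 by default", {
  ctl <- fcnbla_control()
  expect_equal(length(ctl$filter_heights) * ctl$filters_per_height +
                 2L * ctl$hidden_size, 550L)
  model <- tiny_model()
  cache <- fcnbla:::forward_doc(model, random_ids(6L, model$vocab))
  expect_length(cache$fus$lF, model$dims$zc + model$dims$zb)
})

test_that("one-dimensional fusion toy equals tanh(l_r + l_w)", {
  par <- list(W = matrix(1, 1, 2), b = 0)
  out <- fcnbla:::fuse_middle(0.3, 0.5, par, "tanh")
  expect_equal(out$pF, tanh(0.8), tolerance = 1e-12)
})

test_that("the blend is the stated convex combination of the three heads", {
  # alpha = 1 collapses onto the local head
  model1 <- tiny_model(control = tiny_control(alpha = 1))
  cache1 <- fcnbla:::forward_doc(model1, random_ids(6L, model1$vocab))
  expect_equal(cache1$f, cache1$sC, tolerance = 1e-12)
  # alpha = 0.3 gives coefficients (0.30, 0.35, 0.35)
  model <- tiny_model(control = tiny_control(alpha = 0.3))
  cache <- fcnbla:::forward_doc(model, random_ids(6L, model$vocab))
  expect_equal(cache$f, 0.3 * cache$sC + 0.35 * cache$sB + 0.35 * cache$sF,
               tolerance = 1e-12)
  # equal heads pass through unchanged for any alpha
  v <- c(0.2, -1, 3)
  for (a in c(0, 0.3, 0.7, 1))
    expect_equal(a * v + (1 - a) / 2 * v + (1 - a) / 2 * v, v)
  expect_error(fcnbla_control(alpha = 1.2), "alpha")
})

test_that("softmax produces the closed-form probabilities", {
  expect_equal(fcnbla:::softmax_stable(rep(0, 10)), rep(0.1, 10))
  expect_equal(fcnbla:::softmax_stable(c(1, 2)),
               c(0.2689414214, 0.7310585786), tolerance = 1e-9)
  p <- fcnbla:::softmax_stable(c(500, 0, 0))
  expect_equal(p[1], 1, tolerance = 1e-12)   # stable for large scores
})

test_that("cross-entropy is zero at certainty, log C at uniformity, additive", {
  lp_certain <- fcnbla:::log_softmax_stable(c(1e4, 0, 0))
  expect_equal(-lp_certain[1], 0, tolerance = 1e-12)
  lp_unif <- fcnbla:::log_softmax_stable(rep(0, 10))
  expect_equal(-lp_unif[3], log(10), tolerance = 1e-12)
  model <- tiny_model()
  ids <- random_ids(5L, model$vocab)
  cache <- fcnbla:::forward_doc(model, ids)
  single <- fcnbla:::doc_nll(cache, 2L)
  expect_equal(single + single,
               sum(rep(fcnbla:::doc_nll(cache, 2L), 2)))  # sum reduction
  expect_true(single > 0)
})

test_that("variant factory builds the documented architectures", {
  expect_error(fcnbla:::variant_spec("NOPE"), "unknown variant")
  full <- tiny_model("FCNBLA")
  cnbl <- tiny_model("CNBL")
  expect_gt(n_parameters(full), n_parameters(cnbl))
  tc <- tiny_model("TCNBLA")
  cache <- fcnbla:::forward_doc(tc, random_ids(6L, tc$vocab))
  expect_length(cache$f, tc$labels$n_classes)
  expect_equal(sum(cache$p), 1, tolerance = 1e-6)
  # CNBL blends only the two branch heads
  cc <- fcnbla:::forward_doc(cnbl, random_ids(6L, cnbl$vocab))
  a <- cnbl$control$alpha
  expect_equal(cc$f, a * cc$sC + (1 - a) * cc$sB, tolerance = 1e-12)
  expect_null(cc$pF)
})

test_that("FNOA equals the full model when attention scores are constant", {
  # zeroing both context vectors makes every attention softmax uniform,
  # which is exactly the masked-mean pooling FNOA substitutes
  full <- tiny_model("FCNBLA")
  full$params$pattn <- lapply(full$params$pattn, function(pa) {
    pa$u <- pa$u * 0; pa
  })
  full$params$wattn$u <- full$params$wattn$u * 0
  noa <- tiny_model("FNOA")
  shared <- intersect(names(noa$params), names(full$params))
  noa$params[shared] <- full$params[shared]
  ids <- random_ids(7L, full$vocab)
  expect_equal(fcnbla:::forward_doc(full, ids)$p,
               fcnbla:::forward_doc(noa, ids)$p, tolerance = 1e-10)
})

test_that("predictions are a probability simplex for random masked inputs", {
  set.seed(60)
  model <- tiny_model()
  for (rep_i in 1:25) {
    Tlen <- sample(1:9, 1)
    ids <- c(random_ids(Tlen, model$vocab),
             rep(model$vocab$pad_id, sample(0:3, 1)))
    cache <- fcnbla:::forward_doc(model, ids)
    expect_true(all(cache$p > 0))
    expect_equal(sum(cache$p), 1, tolerance = 1e-6)
  }
})
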