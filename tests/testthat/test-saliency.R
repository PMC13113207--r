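test_that("attributions are exact for the linear architecture at any step count", {
  w <- separable_fit()
  lin <- train_with_checkpoints(w$train, d = 8L, hidden = 0L, epochs = 5L,
                                K = 2L, seed = 3L)$model
  toks <- w$test$tokens[[1]]
  ids <- toks[toks != 0L]
  L <- length(ids)
  X <- lin$E[ids + 1L, , drop = FALSE]
  for (steps in c(1L, 4L, 50L)) {
    for (method in c("gauss_legendre", "riemann_left")) {
      ig <- integrated_gradients(lin, toks, target = 1L, baseline = "zero",
                                 steps = steps, method = method)
      closed <- X * matrix(rep(lin$W2[, 1] / L, each = L), nrow = L)
      expect_equal(ig$attributions, closed, tolerance = 1e-9)
      expect_lt(ig$completeness_gap, 1e-9)
    }
  }
})

test_that("a baseline equal to the input yields zero attributions", {
  w <- separable_fit()
  m <- w$fit$model
  toks <- w$test$tokens[[2]]
  ids <- toks[toks != 0L]
  X <- m$E[ids + 1L, , drop = FALSE]
  ig <- integrated_gradients(m, toks, target = 1L, baseline = X, steps = 16L)
  expect_equal(max(abs(ig$attributions)), 0)
  expect_lt(ig$completeness_gap, 1e-12)
})

test_that("completeness improves with quadrature resolution on the nonlinear model", {
  w <- separable_fit()
  m <- w$fit$model
  set.seed(9)
  idx <- sample(n_records(w$test), 20)
  worse <- 0
  for (i in idx) {
    toks <- w$test$tokens[[i]]
    gaps <- vapply(c(8L, 32L, 128L), function(s) {
      integrated_gradients(m, toks, target = w$test$label_index[i],
                           steps = s)$completeness_gap
    }, numeric(1))
    expect_lt(gaps[3], 1e-3)
    if (any(diff(gaps) > 1e-12)) worse <- worse + 1
    # oracle: a 4096-step Riemann sum pins the true integral
    oracle <- integrated_gradients(m, toks, target = w$test$label_index[i],
                                   steps = 4096L, method = "riemann_left")
    ig128 <- integrated_gradients(m, toks, target = w$test$label_index[i],
                                  steps = 128L)
    expect_equal(sum(ig128$attributions), sum(oracle$attributions),
                 tolerance = 1e-3)
  }
  expect_lte(worse, 2)   # monotone non-increase up to isolated ties
  expect_error(integrated_gradients(m, w$test$tokens[[1]], 1L, steps = 0L),
               "steps")
  expect_error(integrated_gradients(m, w$test$tokens[[1]], 1L,
                                    baseline = matrix(0, 1, 1)), "shape")
})

test_that("tokens with identical embeddings and positions get equal attributions", {
  w <- separable_fit()
  m <- w$fit$model
  toks <- w$test$tokens[[1]]
  ids <- toks[toks != 0L]
  # duplicate a token: under mean pooling both copies are interchangeable
  dup <- c(ids, ids[1])
  ig <- integrated_gradients(m, dup, target = 1L, steps = 32L)
  expect_equal(ig$token_scores[1], ig$token_scores[length(dup)],
               tolerance = 1e-12)
})

test_that("word aggregation conserves attribution mass", {
  words <- aggregate_to_words(c(0.2, 0.3, -0.1), c(1L, 1L, 2L))
  expect_equal(words$attribution, c(0.5, -0.1))
  expect_equal(max(abs(words$display)), 1)
  expect_equal(sum(words$attribution), sum(c(0.2, 0.3, -0.1)))
  zero <- aggregate_to_words(c(0, 0), c(1L, 2L))
  expect_equal(zero$display, c(0, 0))
  expect_error(aggregate_to_words(c(1, 2), c(1L, NA)), "word map")
})

test_that("the saliency report pairs codes with titles for both outcomes", {
  w <- separable_fit()
  out_tsv <- withr::local_tempfile(fileext = ".tsv")
  out_html <- withr::local_tempfile(fileext = ".html")
  rep <- render_saliency_report(w$fit$model, w$test, w$codebook,
                                n_correct = 3L, n_incorrect = 3L,
                                out_html = out_html, out_tsv = out_tsv,
                                steps = 16L)
  tab <- rep$table
  expect_gte(nrow(tab), 3L)
  expect_equal(tab$correct, tab$true_code == tab$pred_code)
  expect_true(all(nzchar(tab$true_title)))
  expect_true(all(nzchar(tab$pred_title)))
  # the reported score is the sum of word attributions
  for (i in seq_along(rep$records)) {
    expect_equal(tab$attribution_score[i],
                 sum(rep$records[[i]]$words$attribution), tolerance = 1e-9)
  }
  expect_true(file.exists(out_html))
  html <- readLines(out_html)
  expect_true(any(grepl("Word Importance", html)))
  expect_true(file.exists(out_tsv))
})

test_that("rule-decisive external-cause words attract the largest attribution", {
  # certificates whose UCOD is an external cause: the external words should
  # carry the top positive attribution in most correctly classified cases
  hits <- 0; total <- 0
  for (seed in c(101, 202, 303, 404, 505)) {
    cfg <- generator_config(n_codes = 40L, seed = seed)
    cb <- build_codebook(cfg)
    certs <- generate_certificates(cb, 700L, cfg)
    sp <- suppressWarnings(split_dataset(certs, seed = seed))
    vocab <- build_vocabulary(render_sentences(sp$train, cb))
    classes <- sort(unique(certs$true_ucod))
    tr <- sentence_records(sp$train, cb, vocab, classes)
    te <- sentence_records(sp$test, cb, vocab, classes)
    fit <- train_with_checkpoints(tr, d = 16L, hidden = 8L, epochs = 15L,
                                  K = 2L, seed = seed)
    z <- predict_logits(fit$model, te)
    pred <- max.col(z, ties.method = "first")
    ext_ucod <- map_code_to_chapter(te$label) == "XX"
    sel <- which(ext_ucod & pred == te$label_index)
    for (i in utils::head(sel, 10)) {
      ar <- attribution_record(fit$model, te, i, steps = 16L)
      ext_title <- cb$title[match(te$label[i], cb$code)]
      ext_words <- tokenize_text(ext_title)$token
      top_word <- ar$words$word[which.max(ar$words$attribution)]
      total <- total + 1
      if (top_word %in% ext_words) hits <- hits + 1
    }
  }
  expect_gte(total, 10)
  expect_gt(hits / total, 0.5)
})
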