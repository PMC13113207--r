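test_that("chapter tables count inputs, targets and accuracy correctly", {
  cb <- tiny_codebook()
  certs <- data.frame(cert_id = c("c1", "c2", "c3", "c4"),
                      sex = "female", age = 70L, stringsAsFactors = FALSE)
  certs$part1 <- list(list("I21.9", "I10"), list("I21.9"), list("N19"),
                      list(c("S02.1"), c("V03.1")))
  certs$part2 <- list(character(), "F03", character(), character())
  certs$true_ucod <- c("I10", "I21.9", "N19", "V03.1")
  class(certs) <- c("death_certificates", "data.frame")
  classes <- c("I10", "I21.9", "N19", "V03.1")
  preds <- data.frame(id = certs$cert_id,
                      predicted = c(1L, 2L, 2L, 4L),
                      label = c(1L, 2L, 3L, 4L),
                      confidence = c(0.9, 0.8, 0.7, 0.95),
                      correct = c(TRUE, TRUE, FALSE, TRUE))
  tab <- chapter_accuracy_table(preds, certs, classes)
  ix <- tab[tab$chapter == "IX", ]
  # inputs: I21.9, I10, I21.9 -> 3 of 7 stated conditions
  expect_equal(ix$input_count, 3L)
  expect_equal(ix$input_percent, round(300 / 7, 3))
  # targets: I10, I21.9 -> 2 of 4 certificates, both correct
  expect_equal(ix$target_count, 2L)
  expect_equal(ix$accuracy, 1)
  xiv <- tab[tab$chapter == "XIV", ]
  expect_equal(xiv$accuracy, 0)
  # chapter XIX appears as input only: null accuracy (the "-" convention)
  xix <- tab[tab$chapter == "XIX", ]
  expect_equal(xix$input_count, 1L)
  expect_true(is.na(xix$accuracy))
  # percent columns each sum to 100 within rounding
  expect_equal(sum(tab$input_percent), 100, tolerance = 0.01)
  expect_equal(sum(tab$target_percent), 100, tolerance = 0.01)
  # conservation
  expect_equal(sum(tab$input_count), 7L)
  expect_equal(sum(tab$target_count), 4L)
  expect_error(chapter_accuracy_table(
    within(preds, id <- paste0(id, "x")), certs, classes), "no matching")
})

test_that("top-k tables rank, cover and degenerate correctly", {
  codes <- c(rep("I25.1", 5), rep("C34.9", 3), "J44.9", "F03")
  tab <- top_k_frequency_table(codes, k = 2L)
  expect_equal(tab$code, c("I25.1", "C34.9"))
  expect_equal(tab$percent, c(50, 30))
  expect_equal(tab$cumulative_percent, c(50, 80))
  expect_true(all(diff(tab$cumulative_percent) >= 0))
  one <- top_k_frequency_table("I10", k = 5L)
  expect_equal(one$percent, 100)
  expect_error(top_k_frequency_table(character()), "no code")
})

test_that("published top-10 coverage sums reproduce the reported shares", {
  ucod <- top_k_frequency_table(reference_top10("ucod"), k = 10L)
  expect_equal(round(ucod$cumulative_percent[10]), 36)
  stated <- top_k_frequency_table(reference_top10("stated"), k = 10L)
  expect_equal(round(stated$cumulative_percent[10], 1), 31.2)
  # the printed titles ride along
  expect_equal(ucod$title[1], "Atherosclerotic heart disease")
})

test_that("confidence group stats use linear-interpolation quartiles", {
  pf <- pf_from(c(0.2, 0.4, 0.6, 0.8), c(TRUE, TRUE, TRUE, TRUE))
  out <- confidence_group_stats(pf, rep("I21.9", 4), grouping = "chapter")
  expect_equal(out$group, "IX")
  expect_equal(out$median, 0.5)
  expect_equal(out$q1, 0.35)
  expect_equal(out$q3, 0.65)
  expect_equal(out$error_rate, 0)
  expect_equal(attr(out, "quartile_method"), "linear interpolation")
  # singleton group: degenerate five-number summary
  one <- confidence_group_stats(pf_from(0.7, FALSE), "C50.9", "class")
  expect_equal(one$median, 0.7)
  expect_equal(one$q3 - one$q1, 0)
  expect_equal(one$error_rate, 1)
  # training counts join on the group key, absent keys count zero
  two <- confidence_group_stats(pf_from(c(0.5, 0.9), c(TRUE, FALSE)),
                                c("I10", "C50.9"), "class",
                                train_counts = c(I10 = 12))
  expect_equal(two$train_count[two$group == "I10"], 12)
  expect_equal(two$train_count[two$group == "C50.9"], 0)
})

test_that("rarely trained classes are less accurate than well-trained ones", {
  w <- separable_fit()
  # build an imbalanced world instead: multi-condition certificates
  cfg <- generator_config(n_codes = 60L, seed = 13L)
  cb <- build_codebook(cfg)
  certs <- generate_certificates(cb, 1500L, cfg)
  sp <- suppressWarnings(split_dataset(certs, seed = 13L))
  vocab <- build_vocabulary(render_sentences(sp$train, cb))
  classes <- sort(unique(certs$true_ucod))
  tr <- sentence_records(sp$train, cb, vocab, classes)
  te <- sentence_records(sp$test, cb, vocab, classes)
  fit <- train_with_checkpoints(tr, d = 32L, hidden = 16L, epochs = 20L,
                                K = 2L, seed = 13L)
  ps <- predict_set(fit$model, te)
  pf <- prediction_frame(ps)
  pf$correct <- classes[pf$predicted] == te$label
  tcounts <- c(table(sp$train$true_ucod))
  stats <- confidence_group_stats(pf, te$label, "class", train_counts = tcounts)
  low <- stats$train_count < 15
  err <- function(sel) stats::weighted.mean(stats$error_rate[sel], stats$n[sel])
  expect_gt(err(low), err(!low))
})
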