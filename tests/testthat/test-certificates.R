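test_that("UCOD selection follows the rule cascade", {
  cb <- tiny_codebook()
  # originating-condition principle: last code of the last used line
  expect_equal(select_true_ucod(list("I21.9", "I10", "N19"), character(), cb), "N19")
  # external cause dominates injuries and everything else
  expect_equal(select_true_ucod(list(c("S02.1"), c("V03.1")), character(), cb), "V03.1")
  expect_equal(select_true_ucod(list("I10", "V03.1", "N19"), character(), cb), "V03.1")
  # ill-defined originating condition is skipped in favour of its antecedent
  expect_equal(select_true_ucod(list("I10", "R99"), character(), cb), "I10")
  # injury originating condition skipped too
  expect_equal(select_true_ucod(list("F03", "S02.1"), character(), cb), "F03")
  # fallback: all candidates excluded -> originating code regardless of flags
  expect_equal(select_true_ucod(list("R99"), character(), cb), "R99")
  expect_equal(select_true_ucod(list("S02.1", "R99"), character(), cb), "R99")
  # Part 2 is never selected by the chain walk
  expect_equal(select_true_ucod(list("I10"), "A41.9", cb), "I10")
  expect_error(select_true_ucod(list(), character(), cb), "no conditions")
  expect_error(select_true_ucod(list("Q99.9"), character(), cb), "not in codebook")
})

test_that("generated certificates satisfy their structural invariants", {
  w <- generated_world()
  certs <- w$certs
  # determinism
  again <- generate_certificates(w$codebook, nrow(certs), w$cfg)
  expect_identical(certs, again)
  nc <- n_conditions(certs)
  expect_true(all(nc >= 1 & nc <= 15))
  expect_true(all(n_lines(certs) >= 1 & n_lines(certs) <= 4))
  # every stated code exists in the codebook
  expect_true(all(unlist(stated_codes(certs)) %in% w$codebook$code))
  # generator self-consistency: stored label equals the rule engine's answer
  recomputed <- vapply(seq_len(nrow(certs)), function(i) {
    select_true_ucod(certs$part1[[i]], certs$part2[[i]], w$codebook)
  }, "")
  expect_identical(certs$true_ucod, recomputed)
})

test_that("external-cause dominance and injury exclusion hold on generated data", {
  w <- generated_world()
  certs <- w$certs
  cb <- w$codebook
  has_ext <- vapply(stated_codes(certs), function(cs) {
    any(cb$is_external_cause[match(cs, cb$code)])
  }, logical(1))
  ucod_ch <- map_code_to_chapter(certs$true_ucod)
  expect_true(all(ucod_ch[has_ext] == "XX"))
  # injuries are never selected: every generated injury is accompanied by
  # its external circumstance, which takes precedence
  expect_true(all(!cb$is_injury[match(certs$true_ucod, cb$code)]))
})

test_that("code frequencies respond to the imbalance exponent", {
  gini <- function(x) {
    x <- sort(x)
    n <- length(x)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
  cb <- build_codebook(generator_config(n_codes = 60L, seed = 2L))
  counts_for <- function(expo) {
    cfg <- generator_config(n_codes = 60L, imbalance_exponent = expo, seed = 2L)
    certs <- generate_certificates(cb, 600L, cfg)
    tab <- table(factor(unlist(stated_codes(certs)), levels = cb$code))
    as.numeric(tab)
  }
  expect_gt(gini(counts_for(2)), gini(counts_for(0)))
})

test_that("fewer distinct codes appear as targets than as stated conditions", {
  w <- generated_world()
  expect_lt(length(unique(w$certs$true_ucod)),
            length(unique(unlist(stated_codes(w$certs)))))
})

test_that("certificate CSV round-trips", {
  w <- generated_world()
  certs <- w$certs[1:50, ]
  class(certs) <- c("death_certificates", "data.frame")
  path <- withr::local_tempfile(fileext = ".csv")
  write_certificates(certs, path)
  back <- read_certificates(path)
  expect_equal(back$cert_id, certs$cert_id)
  expect_equal(back$age, certs$age)
  expect_equal(back$part1, certs$part1)
  expect_equal(back$part2, certs$part2)
  expect_equal(back$true_ucod, certs$true_ucod)
})

test_that("splits are exact, disjoint and stratified", {
  w <- generated_world()
  certs <- w$certs
  sp <- suppressWarnings(
    split_dataset(certs, c(train = 0.8, test = 0.1, validation = 0.1), seed = 1L))
  expect_equal(nrow(sp$train), 640L)
  expect_equal(nrow(sp$test), 80L)
  expect_equal(nrow(sp$validation), 80L)
  expect_length(intersect(sp$train$cert_id, sp$test$cert_id), 0L)
  expect_length(intersect(sp$train$cert_id, sp$validation$cert_id), 0L)
  # classes with >= 10 members keep a train share within one member of 80%
  big <- names(which(table(certs$true_ucod) >= 10))
  for (cls in big) {
    m <- sum(certs$true_ucod == cls)
    in_train <- sum(sp$train$true_ucod == cls)
    expect_lte(abs(in_train - 0.8 * m), 1 + 1e-9)
  }
  expect_error(split_dataset(certs[0, ]), "no certificates")
  expect_error(split_dataset(certs, c(train = 0.9, test = 0.2, validation = 0.1)),
               "sum to at most 1")
})

test_that("held-out codes are absent from train but observable in test", {
  w <- generated_world()
  certs <- w$certs
  counts <- sort(train_code_counts(certs), decreasing = TRUE)
  # pick a moderately common non-external code so it surely lands in test
  cb <- w$codebook
  cand <- names(counts)[!cb$is_external_cause[match(names(counts), cb$code)]]
  q <- cand[5]
  sp <- suppressWarnings(split_dataset(certs, seed = 2L, ood_holdout = q))
  expect_false(q %in% unlist(stated_codes(sp$train)))
  expect_true(q %in% unlist(stated_codes(sp$test)))
})
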