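test_that("the raw score reproduces hand-computed variance examples", {
  # build two fake one-token snapshots by hand: gradients 1 and 3 across
  # K = 2 checkpoints give population variance ((1-2)^2 + (3-2)^2)/2 = 1
  mk <- function(w) {
    structure(list(E = matrix(c(0, 1), 2, 1), W1 = NULL, b1 = NULL,
                   W2 = matrix(w, 1, 1), b2 = 0,
                   config = list(), classes = "A", vocab_size = 2L),
              class = "text_classifier")
  }
  cps <- structure(list(models = list(mk(1), mk(3)), epochs = 1:2),
                   class = "checkpoint_set")
  expect_equal(instance_vog(cps, tokens = 1L, p = 1L, layer = "logit"), 1)
  # identical gradients at every checkpoint: zero variance
  cps0 <- structure(list(models = list(mk(2), mk(2)), epochs = 1:2),
                    class = "checkpoint_set")
  expect_equal(instance_vog(cps0, tokens = 1L, p = 1L, layer = "logit"), 0)
  expect_error(instance_vog(structure(list(models = list(mk(1)), epochs = 1L),
                                      class = "checkpoint_set"),
                            tokens = 1L, p = 1L), "at least 2 checkpoints")
})

test_that("vectorised scoring equals the naive per-cell loop", {
  w <- separable_fit()
  set.seed(21)
  idx <- sample(n_records(w$test), 100, replace = TRUE)
  for (i in idx) {
    p <- sample(length(w$classes), 1)
    for (layer in c("softmax", "logit")) {
      expect_equal(
        instance_vog(w$fit$checkpoints, w$test$tokens[[i]], p, layer = layer),
        naive_vog(w$fit$checkpoints, w$test$tokens[[i]], p, layer = layer),
        tolerance = 1e-10)
    }
  }
})

test_that("scaling all gradients by c scales the score by c^2", {
  w <- separable_fit()
  cps <- w$fit$checkpoints
  # doubling W2 doubles every logit gradient in the linear chain rule
  scaled <- cps
  scaled$models <- lapply(cps$models, function(m) { m$W2 <- 3 * m$W2; m })
  toks <- w$test$tokens[[2]]
  # compare on the linear layer where the scaling is exact
  lin <- lapply(cps$models, function(m) { m$W1 <- NULL; m$b1 <- NULL; m })
  lin_scaled <- lapply(lin, function(m) { m$W2 <- 3 * m$W2; m })
  mk <- function(models) structure(list(models = models, epochs = cps$epochs),
                                   class = "checkpoint_set")
  v1 <- instance_vog(mk(lin), toks, 1L, layer = "logit")
  v9 <- instance_vog(mk(lin_scaled), toks, 1L, layer = "logit")
  expect_equal(v9, 9 * v1, tolerance = 1e-10)
})

test_that("raw scores are invariant under token reordering", {
  w <- separable_fit()
  toks <- w$test$tokens[[3]]
  set.seed(8)
  perm <- sample(toks)
  expect_equal(instance_vog(w$fit$checkpoints, toks, 1L),
               instance_vog(w$fit$checkpoints, perm, 1L), tolerance = 1e-12)
})

test_that("normalisation centres classes and clips the global score", {
  vr <- data.frame(cert_id = c("a", "b", "c", "d"),
                   p = 1L, raw_vog = c(0, 2, 1, 5),
                   label_index = c(1L, 1L, 2L, 2L), n_tokens = 5L)
  class(vr) <- c("vog_records", "data.frame")
  out <- normalize_vog(vr)
  expect_equal(out$class_norm_vog, c(-1, 1, -2, 2))
  expect_equal(mean(out$class_norm_vog[out$label_index == 1]), 0)
  expect_true(all(out$global_norm_vog >= -1 & out$global_norm_vog <= 1))
  # an extreme score clips to exactly 1
  vr2 <- vr
  vr2$raw_vog <- c(1, 1.0001, 1, 100)
  out2 <- normalize_vog(vr2)
  expect_equal(max(out2$global_norm_vog), 1)
  # all-identical scores cannot be normalised
  vr3 <- vr
  vr3$raw_vog <- rep(2, 4)
  expect_error(normalize_vog(vr3), "zero global SD")
})

test_that("ranking preserves ids and flags unseen codes and extreme scores", {
  set.seed(14)
  n <- 1000
  vr <- data.frame(cert_id = sprintf("c%04d", 1:n), p = 1L,
                   raw_vog = rexp(n), label_index = sample(1:5, n, TRUE),
                   n_tokens = 10L)
  class(vr) <- c("vog_records", "data.frame")
  vr <- normalize_vog(vr)
  stated <- replicate(n, sample(c("A10", "B20", "C30"), 2), simplify = FALSE)
  stated[[17]] <- c("Q99", "A10")   # states a code with zero occurrences
  counts <- c(A10 = 50L, B20 = 20L, C30 = 10L)
  ranked <- rank_and_flag(vr, stated, counts, flag_quantile = 0.95)
  expect_setequal(ranked$cert_id, vr$cert_id)
  expect_true(all(diff(ranked$global_norm_vog) <= 0))
  expect_true(ranked$flag_ood[ranked$cert_id == "c0017"])
  expect_true(ranked$flag_unseen_code[ranked$cert_id == "c0017"])
  n_high <- sum(ranked$flag_high_vog)
  expect_gt(n_high, 20)
  expect_lt(n_high, 80)
})

test_that("frequency analysis partitions records and validates its ranges", {
  vr <- data.frame(cert_id = c("a", "b", "c"), p = 1L,
                   raw_vog = c(1, 2, 3), label_index = 1:3, n_tokens = 4L,
                   global_norm_vog = c(0.5, -0.5, 0.1),
                   class_norm_vog = 0, global_z = c(0.5, -0.5, 0.1))
  class(vr) <- c("vog_records", "data.frame")
  stated <- list("A10", "B20", c("A10", "B20"))
  counts <- c(A10 = 0L, B20 = 500L)
  fa <- vog_frequency_analysis(vr, stated, counts)
  expect_equal(sum(fa$table$n), 3L)
  expect_equal(fa$table$n[fa$table$lo == 0], 2L)   # a and the min(0,500) record
  expect_equal(fa$table$mean_vog[fa$table$lo == 0], mean(c(0.5, 0.1)))
  bad <- data.frame(lo = c(0, 1), hi = c(2, Inf))
  expect_error(vog_frequency_analysis(vr, stated, counts, ranges = bad),
               "partition")
})

test_that("difficulty correlations behave at the extremes", {
  x <- c(1, 2, 3, 4, 5)
  out <- difficulty_correlations(x, x, rev(x))
  expect_equal(out$pearson_conditions, 1)
  expect_equal(out$kendall_conditions, 1)
  expect_equal(out$kendall_lines, -1)
  set.seed(2)
  a <- rnorm(10000); b <- rnorm(10000)
  out2 <- difficulty_correlations(a, b, b)
  expect_lt(abs(out2$pearson_conditions), 0.03)
  expect_lt(abs(out2$kendall_conditions), 0.03)
  expect_error(difficulty_correlations(c(1, 2), c(1, 2), c(1, 2)), "at least 3")
  expect_error(difficulty_correlations(x, rep(1, 5), x), "zero variance")
})
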