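test_that("binning reproduces the worked four-prediction example", {
  pf <- pf_from(c(0.95, 0.95, 0.55, 0.65), c(TRUE, TRUE, FALSE, TRUE))
  bins <- bin_predictions(pf, M = 10L)
  expect_equal(attr(bins, "n"), 4L)
  b10 <- bins[bins$bin == 10, ]
  expect_equal(b10$count, 2L)
  expect_equal(b10$accuracy, 1)
  expect_equal(b10$confidence, 0.95)
  b6 <- bins[bins$bin == 6, ]
  expect_equal(b6$count, 1L)
  expect_equal(b6$accuracy, 0)
  expect_equal(b6$confidence, 0.55)
  b7 <- bins[bins$bin == 7, ]
  expect_equal(b7$count, 1L)
  expect_equal(b7$accuracy, 1)
  expect_equal(b7$confidence, 0.65)
  rep <- calibration_errors(bins)
  expect_equal(rep$ece, 25.0)
  expect_equal(rep$mce, 55.0)
})

test_that("bin boundaries are half-open with the top bin closed", {
  pf <- pf_from(c(1, 1, 1), c(TRUE, TRUE, FALSE))
  bins <- bin_predictions(pf, M = 10L)
  expect_equal(bins$count[10], 3L)
  expect_equal(sum(bins$count), 3L)
  # exact boundary 0.6 belongs to (0.5, 0.6]
  pf2 <- pf_from(0.6, TRUE)
  bins2 <- bin_predictions(pf2, M = 10L)
  expect_equal(bins2$count[6], 1L)
  # M = 1 degenerates to overall accuracy and mean confidence
  pf3 <- pf_from(c(0.3, 0.9), c(FALSE, TRUE))
  bins3 <- bin_predictions(pf3, M = 1L)
  expect_equal(bins3$accuracy, 0.5)
  expect_equal(bins3$confidence, 0.6)
  expect_error(bin_predictions(pf3[0, ], 10L), "no predictions")
})

test_that("perfect calibration yields zero errors; ECE never exceeds MCE", {
  # construction: bin acc equals bin conf exactly
  pf <- pf_from(rep(c(0.75, 0.75, 0.75, 0.75), 5),
                rep(c(TRUE, TRUE, TRUE, FALSE), 5))
  rep0 <- calibration_errors(bin_predictions(pf, 10L))
  expect_equal(rep0$ece, 0)
  expect_equal(rep0$mce, 0)

  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    pf <- pf_from(stats::runif(n, 1 / 4, 1), sample(c(TRUE, FALSE), n, TRUE))
    rep1 <- calibration_errors(bin_predictions(pf, sample(c(5L, 10L, 15L), 1)))
    expect_lte(rep1$ece, rep1$mce + 1e-12)
    expect_gte(rep1$ece, 0)
    expect_lte(rep1$mce, 100)
    # permutation invariance
    perm <- sample(n)
    rep2 <- calibration_errors(bin_predictions(pf[perm, ], attr(
      bin_predictions(pf, 10L), "M")))
    rep1b <- calibration_errors(bin_predictions(pf, 10L))
    expect_equal(rep2$ece, rep1b$ece)
    expect_equal(rep2$mce, rep1b$mce)
  }
})

test_that("temperature scaling preserves the argmax and the softmax identity", {
  z <- c(2, 0)
  p <- apply_temperature(z, 2)
  expect_equal(as.numeric(p), c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)),
               tolerance = 1e-12)
  expect_equal(as.numeric(apply_temperature(z, 1)), as.numeric(softmax(z)))
  set.seed(4)
  Z <- matrix(rnorm(60), 20, 3)
  for (T in c(0.5, 1, 3)) {
    P <- apply_temperature(Z, T)
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9)
    expect_equal(max.col(P, ties.method = "first"),
                 max.col(Z, ties.method = "first"))
  }
  expect_error(apply_temperature(z, 0), "positive")
})

test_that("fitted temperature recovers the sampling temperature", {
  for (Tstar in c(1, 2.5)) {
    ps <- generate_calibrated_logits(20000, 10, true_temperature = Tstar,
                                     seed = 31)
    tm <- fit_temperature(ps)
    expect_false(tm$bound_hit)
    expect_lt(abs(tm$T - Tstar) / Tstar, 0.06)
    # cross-check against a coarse NLL grid
    grid <- seq(max(0.1, Tstar - 1), Tstar + 1, by = 0.01)
    nll <- vapply(grid, function(T) mortexplain:::.nll_at(ps, T), numeric(1))
    expect_lt(abs(grid[which.min(nll)] - tm$T), 0.05)
  }
})

test_that("degenerate validation sets drive the temperature to a bound", {
  ps <- generate_calibrated_logits(1, 3, seed = 2, labels_from_argmax = TRUE)
  expect_warning(tm <- fit_temperature(ps), "bound")
  expect_equal(tm$T, 0.05)
  expect_true(tm$bound_hit)
})

test_that("reliability tables carry gaps for both stages", {
  pf <- pf_from(c(0.95, 0.95, 0.55, 0.65), c(TRUE, TRUE, FALSE, TRUE))
  bins <- bin_predictions(pf, 10L)
  tab <- reliability_data(bins, bins)
  expect_equal(nrow(tab), 20L)
  filled <- tab[tab$stage == "before" & tab$count > 0, ]
  expect_equal(sort(filled$gap), c(0.05, 0.35, 0.55))
  expect_equal(tab$identity, tab$midpoint)
  b5 <- bin_predictions(pf, 5L)
  expect_error(reliability_data(bins, b5), "same number of bins")
})

test_that("scaling a miscalibrated prediction set lowers its ECE", {
  val <- generate_calibrated_logits(8000, 8, true_temperature = 2.5, seed = 7)
  test <- generate_calibrated_logits(8000, 8, true_temperature = 2.5, seed = 8)
  cal <- calibrate_predictions(test, val)
  expect_lt(cal$after$ece, cal$before$ece)
  expect_gt(cal$temperature$T, 1.5)
})
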