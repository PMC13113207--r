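#' Bin predictions by confidence
#'
#' Groups predictions into `M` equal-width half-open confidence bins
#' `((m-1)/M, m/M]`; a confidence of exactly 0 (impossible for a softmax
#' maximum, but tolerated) is assigned to bin 1. Per-bin accuracy is the
#' fraction of correct predictions, per-bin confidence the mean predicted
#' confidence.
#'
#' @param preds a data.frame as returned by [prediction_frame()] (columns
#'   `confidence` and `correct`).
#' @param M number of bins (>= 1).
#' @return object of class `calibration_bins`: data.frame with one row per
#'   bin (`bin`, `lower`, `upper`, `midpoint`, `count`, `accuracy`,
#'   `confidence`; accuracy/confidence are NA for empty bins), with
#'   attributes `M` and `n`.
#' @export
bin_predictions <- function(preds, M = 10L) {
  if (M < 1) stop("M must be >= 1")
  if (nrow(preds) == 0) stop("no predictions to bin")
  conf <- preds$confidence
  if (any(conf < 0 | conf > 1)) stop("confidences must lie in [0, 1]")
  bin <- pmax(1L, ceiling(conf * M - 1e-12))
  bin <- pmin(bin, M)
  out <- data.frame(bin = seq_len(M),
                    lower = (seq_len(M) - 1) / M,
                    upper = seq_len(M) / M,
                    midpoint = (seq_len(M) - 0.5) / M)
  out$count <- tabulate(bin, nbins = M)
  acc <- conf_mean <- rep(NA_real_, M)
  for (m in which(out$count > 0)) {
    sel <- bin == m
    acc[m] <- mean(preds$correct[sel])
    conf_mean[m] <- mean(conf[sel])
  }
  out$accuracy <- acc
  out$confidence <- conf_mean
  attr(out, "M") <- as.integer(M)
  attr(out, "n") <- nrow(preds)
  class(out) <- c("calibration_bins", "data.frame")
  out
}

#' Expected and maximum calibration error
#'
#' ECE is the count-weighted average of the absolute gap between per-bin
#' accuracy and per-bin mean confidence; MCE the largest such gap over
#' non-empty bins. Both are reported on the percent scale (x 100); empty
#' bins contribute zero weight to ECE and are excluded from the MCE maximum.
#'
#' @param bins a [bin_predictions()] result.
#' @return object of class `calibration_report`: list with `ece`, `mce`
#'   (percent scale), `per_bin` (bin table with a `gap` column), `n`, and
#'   `scale = "percent"`.
#' @export
calibration_errors <- function(bins) {
  stopifnot(inherits(bins, "calibration_bins"))
  n <- attr(bins, "n")
  gap <- abs(bins$accuracy - bins$confidence)
  filled <- bins$count > 0
  ece <- sum((bins$count[filled] / n) * gap[filled]) * 100
  mce <- max(gap[filled]) * 100
  per_bin <- as.data.frame(bins)
  per_bin$gap <- gap
  structure(list(ece = ece, mce = mce, per_bin = per_bin, n = n,
                 scale = "percent"),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> ECE = %.2f%%, MCE = %.2f%% over %d predictions\n",
              x$ece, x$mce, x$n))
  invisible(x)
}

#' Temperature-scale logits
#'
#' Divides the logits by `T` before the softmax. A monotone transform of
#' each row, so predicted class labels are unchanged for any `T > 0`.
#'
#' @param logits numeric matrix (or vector for a single prediction).
#' @param T positive scalar temperature.
#' @return probability matrix with rows summing to 1.
#' @export
apply_temperature <- function(logits, T) {
  if (!is.numeric(T) || length(T) != 1 || T <= 0) stop("T must be a positive scalar")
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  softmax(logits / T)
}

# mean negative log-likelihood of the true labels at temperature T
.nll_at <- function(pset, T) {
  z <- pset$logits / T
  m <- apply(z, 1, max)
  lse <- m + log(rowSums(exp(z - m)))
  mean(lse - z[cbind(seq_len(nrow(z)), pset$labels)])
}

#' Fit a scalar temperature on held-out predictions
#'
#' Finds the temperature minimising the mean negative log-likelihood of the
#' true labels under `softmax(z / T)` (the standard single-parameter
#' post-hoc calibration), by bounded scalar search on `T` in `[0.05, 20]` to
#' a tolerance of 1e-4. An ECE-minimising objective is available as an
#' option. If the objective keeps improving into a boundary (e.g. an
#' all-correct validation set whose likelihood grows without bound as
#' `T -> 0`), the boundary temperature is returned with `bound_hit = TRUE`
#' and a warning.
#'
#' @param validation a [prediction_set()] with at least two classes
#'   represented among the labels.
#' @param objective `"nll"` (default) or `"ece"`.
#' @param bins bin count used when `objective = "ece"`.
#' @param lower,upper search bounds for `T`.
#' @return object of class `temperature_model`: list with `T`, `objective`,
#'   `value` (objective at the optimum) and `bound_hit`.
#' @export
fit_temperature <- function(validation, objective = c("nll", "ece"),
                            bins = 10L, lower = 0.05, upper = 20) {
  objective <- match.arg(objective)
  if (nrow(validation$logits) == 0) stop("empty validation set")
  fn <- switch(objective,
    nll = function(T) .nll_at(validation, T),
    ece = function(T) {
      pf <- prediction_frame(validation, temperature = T)
      calibration_errors(bin_predictions(pf, M = bins))$ece
    })
  opt <- stats::optimize(fn, interval = c(lower, upper), tol = 1e-4)
  T_hat <- opt$minimum
  # a boundary at least as good as the interior optimum means the objective
  # keeps improving into the bound (degenerate likelihood)
  bound_hit <- FALSE
  if (fn(lower) <= opt$objective + 1e-12) { T_hat <- lower; bound_hit <- TRUE }
  if (fn(upper) <= opt$objective + 1e-12) { T_hat <- upper; bound_hit <- TRUE }
  if (bound_hit) {
    warning("temperature search hit a bound; the objective may be degenerate")
  }
  structure(list(T = T_hat, objective = objective,
                 value = fn(T_hat), bound_hit = bound_hit),
            class = "temperature_model")
}

#' @export
print.temperature_model <- function(x, ...) {
  cat(sprintf("<temperature_model> T = %.4f (%s objective = %.6f%s)\n",
              x$T, x$objective, x$value,
              if (x$bound_hit) ", bound hit" else ""))
  invisible(x)
}

#' Reliability-diagram data, before and after scaling
#'
#' Emits the per-bin table behind a confidence histogram and reliability
#' diagram: midpoint, count, accuracy, mean confidence and gap for both bin
#' sets, with the identity line as the calibration reference.
#'
#' @param bins_before,bins_after [bin_predictions()] results sharing the
#'   same `M`.
#' @return data.frame with `M` rows per stage (`stage` in
#'   `"before"`/`"after"`) and columns `bin`, `midpoint`, `count`,
#'   `accuracy`, `confidence`, `gap`, `identity`.
#' @export
reliability_data <- function(bins_before, bins_after) {
  if (!identical(attr(bins_before, "M"), attr(bins_after, "M"))) {
    stop("bin sets must share the same number of bins M")
  }
  one <- function(bins, stage) {
    data.frame(stage = stage, bin = bins$bin, midpoint = bins$midpoint,
               count = bins$count, accuracy = bins$accuracy,
               confidence = bins$confidence,
               gap = abs(bins$accuracy - bins$confidence),
               identity = bins$midpoint,
               stringsAsFactors = FALSE)
  }
  rbind(one(bins_before, "before"), one(bins_after, "after"))
}

#' One-call calibration report for a prediction set
#'
#' Fits a temperature on a validation set, then reports ECE/MCE on an
#' evaluation set before and after scaling, plus the reliability-diagram
#' table.
#'
#' @param eval_set evaluation [prediction_set()].
#' @param validation_set held-out [prediction_set()] used to fit `T`.
#' @param M bin count.
#' @param objective passed to [fit_temperature()].
#' @return list with `temperature` (a `temperature_model`), `before`,
#'   `after` (two `calibration_report`s) and `reliability` (the plot table).
#' @export
calibrate_predictions <- function(eval_set, validation_set, M = 10L,
                                  objective = "nll") {
  tm <- fit_temperature(validation_set, objective = objective, bins = M)
  pf_before <- prediction_frame(eval_set, temperature = 1)
  pf_after <- prediction_frame(eval_set, temperature = tm$T)
  b_before <- bin_predictions(pf_before, M)
  b_after <- bin_predictions(pf_after, M)
  list(temperature = tm,
       before = calibration_errors(b_before),
       after = calibration_errors(b_after),
       reliability = reliability_data(b_before, b_after))
}
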