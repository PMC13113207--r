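#' Prediction sets
#'
#' A `prediction_set` couples an n x k logit matrix with integer true labels
#' (1-based class indices) and a provenance block recording where the logits
#' came from (a trained model or the synthetic sampler) and, when known, the
#' temperature at which labels were drawn.
#'
#' @param logits numeric matrix, one row per prediction, one column per class.
#' @param labels integer vector of true class indices in `1..ncol(logits)`.
#' @param provenance list; free-form, typically `source`, `true_temperature`,
#'   `seed`.
#' @param ids optional character ids, one per row.
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(logits, labels, provenance = list(source = "model"),
                           ids = NULL) {
  logits <- as.matrix(logits)
  labels <- as.integer(labels)
  if (nrow(logits) != length(labels)) stop("logits and labels disagree in length")
  if (any(labels < 1 | labels > ncol(logits))) stop("labels outside 1..k")
  if (is.null(ids)) ids <- sprintf("pred-%06d", seq_len(nrow(logits)))
  structure(list(ids = ids, logits = logits, labels = labels,
                 provenance = provenance),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> ", nrow(x$logits), " predictions over ",
      ncol(x$logits), " classes (source: ",
      x$provenance$source %||% "unknown", ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable softmax over matrix rows
#'
#' @param z numeric matrix (or vector, treated as one row).
#' @return matrix of the same shape with rows summing to 1.
#' @export
softmax <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  m <- apply(z, 1, max)
  e <- exp(z - m)
  e / rowSums(e)
}

#' Per-prediction records: probabilities, predicted label, confidence
#'
#' Derives the per-record quantities used throughout calibration and
#' reporting, optionally after temperature scaling of the logits. Argmax ties
#' break toward the lowest class index.
#'
#' @param pset a [prediction_set()].
#' @param temperature positive scalar divisor applied to the logits before
#'   the softmax (1 = raw model output).
#' @return data.frame with columns `id`, `predicted`, `label`, `confidence`,
#'   `correct`.
#' @export
prediction_frame <- function(pset, temperature = 1) {
  if (temperature <= 0) stop("temperature must be > 0")
  p <- softmax(pset$logits / temperature)
  pred <- max.col(p, ties.method = "first")
  data.frame(
    id = pset$ids,
    predicted = pred,
    label = pset$labels,
    confidence = p[cbind(seq_len(nrow(p)), pred)],
    correct = pred == pset$labels,
    stringsAsFactors = FALSE
  )
}

#' Sample a prediction set with known miscalibration
#'
#' Draws logit vectors with i.i.d. normal components (default SD 2, spreading
#' confidences across every bin), then samples the true label of each record
#' from `softmax(z / true_temperature)`. By construction the raw softmax
#' probabilities are perfectly calibrated in expectation only when
#' `true_temperature == 1`; dividing the logits by `true_temperature` always
#' restores calibration, which is the basis of the temperature-recovery
#' checks.
#'
#' @param n number of predictions (>= 1).
#' @param k number of classes (>= 2).
#' @param true_temperature positive real; the temperature at which labels are
#'   sampled.
#' @param seed integer seed.
#' @param logit_sd standard deviation of the logit components.
#' @param labels_from_argmax if TRUE, labels are set to `argmax(z)` instead
#'   of sampled, producing an accuracy-1 prediction set.
#' @return a [prediction_set()] with provenance
#'   `list(source = "synthetic", true_temperature, seed)`.
#' @export
generate_calibrated_logits <- function(n, k, true_temperature = 1, seed = 1L,
                                       logit_sd = 2, labels_from_argmax = FALSE) {
  if (n < 1) stop("n must be >= 1")
  if (k < 2) stop("k must be >= 2")
  if (true_temperature <= 0) stop("true_temperature must be > 0")
  old <- .restore_seed()
  set.seed(seed)
  z <- matrix(stats::rnorm(n * k, sd = logit_sd), nrow = n, ncol = k)
  if (labels_from_argmax) {
    labels <- max.col(z, ties.method = "first")
  } else {
    p <- softmax(z / true_temperature)
    u <- stats::runif(n)
    cum <- t(apply(p, 1, cumsum))
    labels <- rowSums(cum < u) + 1L
  }
  .reinstate_seed(old)
  prediction_set(z, labels,
                 provenance = list(source = "synthetic",
                                   true_temperature = true_temperature,
                                   seed = seed))
}

#' Write / read a prediction set as JSONL
#'
#' First line is a provenance header object; each following line is one
#' record with fields `id`, `logits` and `label`.
#'
#' @param pset a [prediction_set()].
#' @param path file path.
#' @return `write_prediction_set` returns `path` invisibly;
#'   `read_prediction_set` a `prediction_set`.
#' @export
write_prediction_set <- function(pset, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(c(list(record_type = "provenance"),
                                pset$provenance), auto_unbox = TRUE), con)
  for (i in seq_len(nrow(pset$logits))) {
    writeLines(jsonlite::toJSON(list(id = pset$ids[i],
                                     logits = unname(pset$logits[i, ]),
                                     label = pset$labels[i]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_prediction_set
#' @export
read_prediction_set <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$record_type, "provenance")) {
    stop("first JSONL line must be the provenance header")
  }
  recs <- lapply(lines[-1], jsonlite::fromJSON)
  logits <- do.call(rbind, lapply(recs, function(r) r$logits))
  prediction_set(logits,
                 vapply(recs, function(r) as.integer(r$label), integer(1)),
                 provenance = header[setdiff(names(header), "record_type")],
                 ids = vapply(recs, function(r) r$id, ""))
}
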