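#' Variance-of-Gradients difficulty score for one record
#'
#' For each training checkpoint, takes the gradient of the class-`p` logit
#' with respect to every non-padding token embedding ([token_gradients()]);
#' then, for every (token, component) cell, computes the variance of that
#' gradient across the `K` checkpoints (population variance, denominator
#' `K`); the raw score is the mean of these per-cell variances over all
#' cells. Instances whose gradients move a lot over training are the ones
#' the model finds hard to pin down.
#'
#' @param checkpoints a `checkpoint_set` with `K >= 2` snapshots.
#' @param tokens integer token-id vector for the record (0 = padding).
#' @param p class index used for the gradient (the true label during
#'   analysis of labelled data, the predicted label otherwise).
#' @param mode `"checkpoint"` (default): variance across checkpoints, the
#'   across-training reading of the score; `"final"`: variance across the
#'   gradient components of the final snapshot only, a single-model
#'   sensitivity variant.
#' @param layer which activation the gradient is taken at: `"softmax"`
#'   (default; the class probability, whose gradient is damped by the
#'   model's confidence and therefore concentrates on uncertain instances)
#'   or `"logit"` (the pre-softmax score). See the methods vignette for why
#'   the softmax layer is the default for difficulty ranking.
#' @return non-negative scalar raw score.
#' @export
instance_vog <- function(checkpoints, tokens, p, mode = c("checkpoint", "final"),
                         layer = c("softmax", "logit")) {
  mode <- match.arg(mode)
  layer <- match.arg(layer)
  K <- length(checkpoints$models)
  if (mode == "checkpoint") {
    if (K < 2) stop("need at least 2 checkpoints for an across-checkpoint variance")
    grads <- lapply(checkpoints$models, token_gradients, tokens = tokens,
                    p = p, layer = layer)
    A <- array(unlist(grads), dim = c(dim(grads[[1]]), K))
    mu <- apply(A, c(1, 2), mean)
    v <- apply(A, 3, function(g) (g - mu)^2)   # cells x K
    mean(rowMeans(matrix(v, ncol = K)))
  } else {
    g <- token_gradients(checkpoints$models[[K]], tokens, p, layer = layer)
    mean(apply(g, 1, function(row) mean((row - mean(row))^2)))
  }
}

#' Score every record of a sentence set
#'
#' @param checkpoints a `checkpoint_set`.
#' @param records a [sentence_records()] object.
#' @param class_of `"true"` to take gradients at the true label,
#'   `"predicted"` to use the final model's prediction.
#' @param mode,layer passed to [instance_vog()].
#' @return data.frame of class `vog_records` with columns `cert_id`, `p`,
#'   `raw_vog`, `label_index` and `n_tokens`; normalised columns are added
#'   by [normalize_vog()].
#' @export
vog_records <- function(checkpoints, records, class_of = c("true", "predicted"),
                        mode = "checkpoint", layer = "softmax") {
  class_of <- match.arg(class_of)
  n <- n_records(records)
  p <- if (class_of == "true") records$label_index else {
    final <- checkpoints$models[[length(checkpoints$models)]]
    max.col(predict_logits(final, records), ties.method = "first")
  }
  raw <- vapply(seq_len(n), function(i) {
    instance_vog(checkpoints, records$tokens[[i]], p[i], mode = mode,
                 layer = layer)
  }, numeric(1))
  out <- data.frame(
    cert_id = records$cert_id,
    p = p,
    raw_vog = raw,
    label_index = records$label_index,
    n_tokens = vapply(records$tokens, function(t) sum(t != 0L), integer(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("vog_records", "data.frame")
  out
}

#' Class-wise and global normalisation of raw scores
#'
#' Handles class imbalance by centering each record's raw score on the mean
#' raw score of its class (`class_norm_vog`); the centred scores are then
#' standardised with their global mean and SD and clipped to `[-1, 1]`
#' (`global_norm_vog`), the scale used in all stratified summaries. The
#' unclipped z-score is retained as `global_z` for downstream statistics.
#'
#' @param vrec a [vog_records()] data.frame with `raw_vog` filled.
#' @param labels class labels, one per record (defaults to the stored
#'   `label_index`).
#' @return `vrec` with `class_norm_vog`, `global_z` and `global_norm_vog`
#'   columns added.
#' @export
normalize_vog <- function(vrec, labels = vrec$label_index) {
  if (length(labels) != nrow(vrec)) stop("labels must align with records")
  class_mean <- stats::ave(vrec$raw_vog, labels, FUN = mean)
  vrec$class_norm_vog <- vrec$raw_vog - class_mean
  s <- stats::sd(vrec$class_norm_vog) * sqrt((nrow(vrec) - 1) / nrow(vrec))
  if (nrow(vrec) < 2 || !is.finite(s) || s == 0) {
    stop("cannot normalise: zero global SD (all scores identical)")
  }
  vrec$global_z <- (vrec$class_norm_vog - mean(vrec$class_norm_vog)) / s
  vrec$global_norm_vog <- pmin(1, pmax(-1, vrec$global_z))
  vrec
}

#' Rank records by difficulty and flag OOD-like ones
#'
#' Sorts descending by the global-normalised score and flags a record as
#' OOD-like when (a) it states any code with zero training occurrences, or
#' (b) its score exceeds the given quantile of the score distribution. Rare
#' and unseen codes are exactly where gradient variance concentrates, which
#' is what makes the score usable as a task-specific OOD signal.
#'
#' @param vrec a normalised [vog_records()] data.frame.
#' @param stated list of character vectors: codes stated per record (same
#'   order), e.g. from [stated_codes()].
#' @param train_code_counts named integer vector: training occurrences per
#'   code (absent names count as zero).
#' @param flag_quantile quantile of `global_norm_vog` above which records
#'   are flagged (default 0.95).
#' @return `vrec` sorted descending by `global_norm_vog`, with logical
#'   columns `flag_unseen_code`, `flag_high_vog`, `flag_ood`.
#' @export
rank_and_flag <- function(vrec, stated, train_code_counts, flag_quantile = 0.95) {
  if (!"global_norm_vog" %in% names(vrec)) stop("normalise records first")
  occ <- function(codes) {
    cnt <- train_code_counts[codes]
    cnt[is.na(cnt)] <- 0
    cnt
  }
  vrec$flag_unseen_code <- vapply(stated, function(cs) any(occ(cs) == 0),
                                  logical(1))
  # threshold on the unclipped z-score: clipping piles extreme records at
  # exactly 1, which would make the clipped quantile degenerate
  score <- if ("global_z" %in% names(vrec)) vrec$global_z else vrec$global_norm_vog
  thr <- stats::quantile(score, flag_quantile, names = FALSE)
  vrec$flag_high_vog <- score > thr
  vrec$flag_ood <- vrec$flag_unseen_code | vrec$flag_high_vog
  vrec <- vrec[order(-vrec$global_norm_vog), , drop = FALSE]
  rownames(vrec) <- NULL
  vrec
}

#' Default frequency ranges for the minimum-occurrence analysis
#'
#' Bands of minimum training occurrence mirroring the full-scale analysis:
#' never seen, 1-2, 3-1000, 1001-5000, 5001-20000, above 20000.
#'
#' @return data.frame with columns `lo`, `hi` (inclusive; `Inf` open-ended).
#' @export
default_frequency_ranges <- function() {
  data.frame(lo = c(0, 1, 3, 1001, 5001, 20001),
             hi = c(0, 2, 1000, 5000, 20000, Inf))
}

#' Difficulty by minimum training occurrence of stated codes
#'
#' Each record is assigned to a band by the minimum training occurrence
#' among its stated codes, and the table reports the mean global-normalised
#' score and record count per band. A log2-binned trend
#' (`log2(min_occurrence + 1)` rounded to integer bins) is attached for the
#' continuous view of the same relationship.
#'
#' @param vrec a normalised [vog_records()] data.frame.
#' @param stated list of stated-code vectors per record.
#' @param train_code_counts named integer vector of training occurrences.
#' @param ranges data.frame of `lo`/`hi` bounds covering `[0, Inf)` without
#'   overlap; defaults to [default_frequency_ranges()].
#' @return list with `table` (per-range `lo`, `hi`, `n`, `mean_vog`) and
#'   `log2_trend` (per log2-bin mean score).
#' @export
vog_frequency_analysis <- function(vrec, stated, train_code_counts,
                                   ranges = default_frequency_ranges()) {
  ranges <- ranges[order(ranges$lo), , drop = FALSE]
  if (ranges$lo[1] != 0 || any(ranges$lo[-1] != utils::head(ranges$hi, -1) + 1) ||
      !is.infinite(ranges$hi[nrow(ranges)])) {
    stop("ranges must partition [0, Inf) without overlap")
  }
  occ <- vapply(stated, function(cs) {
    cnt <- train_code_counts[cs]
    cnt[is.na(cnt)] <- 0
    min(cnt)
  }, numeric(1))
  band <- findInterval(occ, ranges$lo)
  tab <- data.frame(lo = ranges$lo, hi = ranges$hi,
                    n = tabulate(band, nbins = nrow(ranges)))
  tab$mean_vog <- vapply(seq_len(nrow(ranges)), function(b) {
    if (tab$n[b] == 0) NA_real_ else mean(vrec$global_norm_vog[band == b])
  }, numeric(1))
  l2 <- round(log2(occ + 1))
  trend <- stats::aggregate(vrec$global_norm_vog, by = list(log2_bin = l2), FUN = mean)
  names(trend)[2] <- "mean_vog"
  trend$n <- as.integer(table(l2)[as.character(trend$log2_bin)])
  list(table = tab, log2_trend = trend, min_occurrence = occ)
}

#' Class-level correlation between difficulty and certificate complexity
#'
#' Pearson (product-moment) and Kendall (rank) correlations between per-class
#' mean difficulty and per-class mean stated-condition / used-line counts —
#' the "is difficulty just length?" check, which at full scale comes out
#' weakly positive.
#'
#' @param class_vog numeric vector: per-class mean score.
#' @param class_conditions numeric vector: per-class mean condition count.
#' @param class_lines numeric vector: per-class mean used Part 1 lines.
#' @return list with `pearson_conditions`, `pearson_lines`,
#'   `kendall_conditions`, `kendall_lines`.
#' @export
difficulty_correlations <- function(class_vog, class_conditions, class_lines) {
  if (length(class_vog) < 3) stop("need at least 3 classes")
  for (v in list(class_vog, class_conditions, class_lines)) {
    if (stats::sd(v) == 0) stop("zero variance makes the correlation undefined")
  }
  list(
    pearson_conditions = stats::cor(class_vog, class_conditions, method = "pearson"),
    pearson_lines = stats::cor(class_vog, class_lines, method = "pearson"),
    kendall_conditions = stats::cor(class_vog, class_conditions, method = "kendall"),
    kendall_lines = stats::cor(class_vog, class_lines, method = "kendall")
  )
}
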