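#' Integrated Gradients over token embeddings
#'
#' Attributes the pre-softmax logit of a target class to each component of
#' each token embedding by integrating the gradient along the straight-line
#' path from a baseline embedding to the actual embedded input, multiplied by
#' the input-minus-baseline difference. The path integral is approximated by
#' Gauss-Legendre quadrature (default) or a left Riemann sum. The
#' completeness property — attributions summing to
#' `F(input) - F(baseline)` — is reported as `completeness_gap`; it vanishes
#' exactly for the linear architecture and shrinks with `steps` for the
#' nonlinear one.
#'
#' @param model a `text_classifier`.
#' @param tokens integer token-id vector (0 = padding; padding positions are
#'   dropped).
#' @param target class index whose logit is attributed.
#' @param baseline `"padding"` (default; the padding embedding — the zero
#'   vector by construction — repeated to input length), `"zero"`, or a
#'   numeric matrix of the same shape as the embedded input.
#' @param steps number of quadrature nodes (>= 1).
#' @param method `"gauss_legendre"` or `"riemann_left"`.
#' @return list with `attributions` (tokens x d matrix), `token_scores`
#'   (per-token component sums, sign preserved), `completeness_gap`,
#'   `delta_F` (`F(input) - F(baseline)`), `steps`, `method`.
#' @export
integrated_gradients <- function(model, tokens, target,
                                 baseline = "padding", steps = 50L,
                                 method = c("gauss_legendre", "riemann_left")) {
  method <- match.arg(method)
  if (steps < 1) stop("steps must be >= 1")
  k <- length(model$classes)
  if (target < 1 || target > k) stop("target class out of range")
  ids <- as.integer(tokens)
  ids <- ids[ids != 0L]
  if (length(ids) == 0L) stop("record contains only padding tokens")
  L <- length(ids)
  X <- model$E[ids + 1L, , drop = FALSE]            # L x d embedded input
  B <- if (is.character(baseline)) {
    switch(baseline,
           padding = matrix(rep(model$E[1, ], each = L), nrow = L),
           zero = matrix(0, L, ncol(X)),
           stop("unknown baseline '", baseline, "'"))
  } else {
    if (!all(dim(as.matrix(baseline)) == dim(X))) {
      stop("baseline shape must match the embedded input (", L, " x ", ncol(X), ")")
    }
    as.matrix(baseline)
  }

  if (method == "gauss_legendre") {
    if (steps == 1L) {
      alphas <- 0.5; weights <- 1   # midpoint: the 1-node Gauss rule
    } else {
      q <- pracma::gaussLegendre(steps, 0, 1)
      alphas <- q$x; weights <- q$w
    }
  } else {
    alphas <- (seq_len(steps) - 1) / steps
    weights <- rep(1 / steps, steps)
  }

  logit_at <- function(M) {
    .forward(model, matrix(colMeans(M), nrow = 1))$logits[1, target]
  }
  # gradient of the target logit w.r.t. the full L x d embedded input at M:
  # pooled gradient spread as 1/L per token
  grad_at <- function(M) {
    g <- .pooled_gradient(model, colMeans(M), target)
    matrix(rep(g / L, each = L), nrow = L)
  }

  acc <- matrix(0, L, ncol(X))
  diff <- X - B
  for (s in seq_along(alphas)) {
    acc <- acc + weights[s] * grad_at(B + alphas[s] * diff)
  }
  attributions <- diff * acc
  delta_F <- logit_at(X) - logit_at(B)
  list(attributions = attributions,
       token_scores = rowSums(attributions),
       completeness_gap = abs(sum(attributions) - delta_F),
       delta_F = delta_F,
       steps = as.integer(steps),
       method = method)
}

#' Aggregate token attributions to words
#'
#' Per-token scalars (component sums, sign preserved) are summed over each
#' word's tokens; display values rescale by the record's maximum absolute
#' word attribution so the strongest word sits at +/-1 (skipped when all
#' attributions are zero). Negative / neutral / positive display values map
#' to the red / white / green shading of the saliency report.
#'
#' @param token_scores numeric vector of per-token scalars (non-padding
#'   tokens, in order).
#' @param word_map integer vector, same length, giving each token's word
#'   index.
#' @return data.frame with `word_index`, `attribution`, `display`.
#' @export
aggregate_to_words <- function(token_scores, word_map) {
  if (length(token_scores) != length(word_map) || anyNA(word_map)) {
    stop("word map must cover every non-padding token")
  }
  agg <- stats::aggregate(token_scores, by = list(word_index = word_map), FUN = sum)
  names(agg)[2] <- "attribution"
  mx <- max(abs(agg$attribution))
  agg$display <- if (mx > 0) agg$attribution / mx else agg$attribution
  agg
}

#' Attribution record for one certificate
#'
#' Runs [integrated_gradients()] on a record and aggregates to words,
#' pairing each word with its text.
#'
#' @param model a `text_classifier`.
#' @param records a [sentence_records()] object.
#' @param i record index.
#' @param target `"predicted"` (default) or `"true"`; which class logit to
#'   attribute.
#' @param ... passed to [integrated_gradients()].
#' @return list of class `attribution_record` with `cert_id`, `true_index`,
#'   `pred_index`, `words` (data.frame of word text, attribution, display),
#'   `attribution_score` (sum of word attributions), `completeness_gap`,
#'   `steps`, `method`.
#' @export
attribution_record <- function(model, records, i,
                               target = c("predicted", "true"), ...) {
  target <- match.arg(target)
  ids <- records$tokens[[i]]
  keep <- ids != 0L
  z <- predict_logits(model, ids)
  pred <- max.col(z, ties.method = "first")
  tgt <- if (target == "predicted") pred else records$label_index[i]
  ig <- integrated_gradients(model, ids, tgt, ...)
  wm <- records$word[[i]][keep]
  words <- aggregate_to_words(ig$token_scores, wm)
  tok_text <- tokenize_text(records$text[i])
  words$word <- vapply(words$word_index, function(w) {
    paste(tok_text$token[tok_text$word == w], collapse = "")
  }, "")
  structure(list(
    cert_id = records$cert_id[i],
    true_index = records$label_index[i],
    pred_index = pred,
    target_index = tgt,
    words = words,
    attribution_score = sum(words$attribution),
    completeness_gap = ig$completeness_gap,
    steps = ig$steps,
    method = ig$method
  ), class = "attribution_record")
}

#' Saliency report over a set of records
#'
#' Builds attribution records for chosen indices (by default a balanced
#' sample of correctly and incorrectly classified records) and renders the
#' failure-analysis layout: true and predicted codes with their titles, the
#' per-word importances on a red/white/green colour scale, and the total
#' attribution score. Written as an HTML page plus a numeric TSV twin.
#'
#' @param model a `text_classifier`.
#' @param records a [sentence_records()] object.
#' @param codebook a `codebook` resolving class codes to titles.
#' @param indices record indices to render; if NULL, up to `n_correct`
#'   correct and `n_incorrect` incorrect records are chosen in order.
#' @param n_correct,n_incorrect sample sizes when `indices` is NULL.
#' @param out_html,out_tsv output paths (NULL to skip writing).
#' @param ... passed to [attribution_record()].
#' @return invisible list with `records` (the attribution records) and
#'   `table` (the TSV data.frame).
#' @export
render_saliency_report <- function(model, records, codebook, indices = NULL,
                                   n_correct = 3L, n_incorrect = 3L,
                                   out_html = NULL, out_tsv = NULL, ...) {
  z <- predict_logits(model, records)
  pred <- max.col(z, ties.method = "first")
  correct <- pred == records$label_index
  if (is.null(indices)) {
    indices <- c(utils::head(which(correct), n_correct),
                 utils::head(which(!correct), n_incorrect))
  }
  code_title <- function(idx) {
    code <- records$classes[idx]
    j <- match(code, codebook$code)
    if (anyNA(j)) stop("class code(s) missing from codebook: ",
                       paste(code[is.na(j)], collapse = ", "))
    list(code = code, title = codebook$title[j])
  }
  recs <- lapply(indices, function(i) attribution_record(model, records, i, ...))

  rows <- lapply(recs, function(r) {
    tru <- code_title(r$true_index); prd <- code_title(r$pred_index)
    data.frame(cert_id = r$cert_id,
               true_code = tru$code, true_title = tru$title,
               pred_code = prd$code, pred_title = prd$title,
               correct = r$true_index == r$pred_index,
               attribution_score = r$attribution_score,
               completeness_gap = r$completeness_gap,
               word_importance = paste(sprintf("%s:%.4f", r$words$word,
                                               r$words$attribution),
                                       collapse = " "),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_tsv)) {
    utils::write.table(tab, out_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(out_html)) {
    writeLines(.saliency_html(recs, tab), out_html)
  }
  invisible(list(records = recs, table = tab))
}

# inline-styled HTML table; green for positive display values, red negative
.saliency_html <- function(recs, tab) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  word_html <- function(words) {
    paste(vapply(seq_len(nrow(words)), function(j) {
      v <- words$display[j]
      col <- if (v >= 0) sprintf("rgba(0,160,0,%.2f)", abs(v))
             else sprintf("rgba(220,0,0,%.2f)", abs(v))
      sprintf("<span style=\"background-color:%s;padding:1px;\">%s</span>",
              col, esc(words$word[j]))
    }, ""), collapse = " ")
  }
  body <- vapply(seq_along(recs), function(i) {
    r <- recs[[i]]; row <- tab[i, ]
    sprintf(paste0("<tr><td>%s</td><td>%s<br/><small>%s</small></td>",
                   "<td>%s<br/><small>%s</small></td><td>%s</td>",
                   "<td style=\"text-align:right\">%.4f</td></tr>"),
            esc(row$cert_id), esc(row$true_code), esc(row$true_title),
            esc(row$pred_code), esc(row$pred_title),
            word_html(r$words), row$attribution_score)
  }, "")
  c("<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    "<title>Saliency report</title></head><body>",
    "<table border=\"1\" cellspacing=\"0\" cellpadding=\"4\">",
    paste0("<tr><th>Certificate</th><th>True Label (UCOD)</th>",
           "<th>Predicted Label (UCOD)</th><th>Word Importance</th>",
           "<th>Attribution Score</th></tr>"),
    body,
    "</table></body></html>")
}
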