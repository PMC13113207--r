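#' Chapter-level accuracy and frequency table
#'
#' The chapter-stratified view of a classifier's behaviour: for each ICD-10
#' chapter, how often it appears among stated (input) conditions, how often
#' as the true UCOD (target), and the top-1 accuracy among records whose
#' true UCOD falls in the chapter. Chapters never occurring as a target get
#' `NA` accuracy (the "-" convention of published chapter tables). Percent
#' columns use a single denominator each — total stated conditions and total
#' certificates respectively — and sum to 100.
#'
#' @param preds a data.frame from [prediction_frame()]; `id` must match
#'   `certs$cert_id`.
#' @param certs the `death_certificates` the predictions refer to.
#' @param classes character vector mapping class indices to codes (as stored
#'   in `sentence_records$classes`).
#' @return data.frame of class `chapter_table`: `chapter`, `chapter_title`,
#'   `input_count`, `input_percent`, `target_count`, `target_percent`,
#'   `accuracy`.
#' @export
chapter_accuracy_table <- function(preds, certs, classes) {
  j <- match(preds$id, certs$cert_id)
  if (anyNA(j)) stop("prediction id(s) with no matching certificate")
  certs <- certs[j, , drop = FALSE]

  stated <- unlist(stated_codes(certs), use.names = FALSE)
  input_ch <- map_code_to_chapter(stated)
  target_ch <- map_code_to_chapter(certs$true_ucod)
  correct <- classes[preds$predicted] == certs$true_ucod

  tab <- icd10_chapters()[, c("chapter", "title")]
  names(tab)[2] <- "chapter_title"
  tab$input_count <- as.integer(table(factor(input_ch, tab$chapter)))
  tab$input_percent <- round(100 * tab$input_count / length(stated), 3)
  tab$target_count <- as.integer(table(factor(target_ch, tab$chapter)))
  tab$target_percent <- round(100 * tab$target_count / nrow(certs), 3)
  tab$accuracy <- vapply(tab$chapter, function(ch) {
    sel <- target_ch == ch
    if (!any(sel)) NA_real_ else mean(correct[sel])
  }, numeric(1))
  keep <- tab$input_count > 0 | tab$target_count > 0
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("chapter_table", "data.frame")
  out
}

#' Top-k frequency table with cumulative coverage
#'
#' Ranks codes by count and reports each one's percent of the total (3
#' decimals, the convention of published mortality frequency tables) along
#' with the running cumulative percent — the "how much of the data do the
#' top k codes cover" summary.
#'
#' @param codes character vector of code observations (e.g. all true UCODs,
#'   or all stated conditions), a named count vector, or a data.frame with
#'   `code`, `count` and optionally `title` and pre-computed `percent`
#'   columns (e.g. a published table whose printed percentages should be
#'   used verbatim).
#' @param k number of rows (>= 1).
#' @param codebook optional `codebook` supplying titles.
#' @return data.frame of class `frequency_table`: `code`, `title`, `count`,
#'   `percent`, `cumulative_percent`.
#' @export
top_k_frequency_table <- function(codes, k = 10L, codebook = NULL) {
  if (k < 1) stop("k must be >= 1")
  given_percent <- NULL
  if (is.data.frame(codes)) {
    if (nrow(codes) == 0) stop("no code observations")
    codes <- codes[order(-codes$count), , drop = FALSE]
    counts <- stats::setNames(as.numeric(codes$count), codes$code)
    if ("percent" %in% names(codes)) {
      given_percent <- stats::setNames(codes$percent, codes$code)
    }
    if (is.null(codebook) && "title" %in% names(codes)) {
      codebook <- data.frame(code = codes$code, title = codes$title,
                             stringsAsFactors = FALSE)
    }
  } else if (!is.null(names(codes))) {
    counts <- sort(stats::setNames(as.numeric(codes), names(codes)),
                   decreasing = TRUE)
  } else {
    counts <- sort(c(table(codes)), decreasing = TRUE)
  }
  if (length(counts) == 0 || sum(counts) == 0) stop("no code observations")
  top <- utils::head(counts, k)
  out <- data.frame(code = names(top), count = as.numeric(top),
                    stringsAsFactors = FALSE)
  out$title <- if (!is.null(codebook)) {
    codebook$title[match(out$code, codebook$code)]
  } else NA_character_
  out$percent <- if (is.null(given_percent)) {
    round(100 * out$count / sum(counts), 3)
  } else {
    as.numeric(given_percent[out$code])
  }
  out$cumulative_percent <- cumsum(out$percent)
  out <- out[, c("code", "title", "count", "percent", "cumulative_percent")]
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Per-group confidence and error-rate summaries
#'
#' The data behind chapter-wise and class-wise confidence plots: for each
#' group (ICD-10 chapter of the true UCOD, or the class itself), the
#' five-number summary of the (optionally temperature-scaled) confidence,
#' the mean confidence, the error rate, the group size, and the group's
#' training-sample count. Quartiles use linear interpolation (stated in the
#' output metadata).
#'
#' @param preds a [prediction_frame()] data.frame.
#' @param true_codes character vector of true UCOD codes aligned with
#'   `preds`.
#' @param grouping `"chapter"` or `"class"`.
#' @param train_counts named vector of training occurrences per group key
#'   (class code or chapter); absent keys count 0.
#' @return data.frame with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `mean_confidence`, `error_rate`,
#'   `train_count`; attribute `quartile_method = "linear interpolation"`.
#' @export
confidence_group_stats <- function(preds, true_codes,
                                   grouping = c("chapter", "class"),
                                   train_counts = NULL) {
  grouping <- match.arg(grouping)
  if (length(true_codes) != nrow(preds)) stop("true_codes must align with preds")
  key <- switch(grouping,
                chapter = map_code_to_chapter(true_codes),
                class = true_codes)
  groups <- unique(key)
  rows <- lapply(groups, function(g) {
    sel <- key == g
    conf <- preds$confidence[sel]
    q <- stats::quantile(conf, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(group = g, n = sum(sel),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
               mean_confidence = mean(conf),
               error_rate = 1 - mean(preds$correct[sel]),
               train_count = if (is.null(train_counts)) NA_real_ else {
                 cnt <- train_counts[g]; if (is.na(cnt)) 0 else as.numeric(cnt)
               },
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "quartile_method") <- "linear interpolation"
  out
}

#' Training occurrences of every stated code
#'
#' @param train_certs the training-split `death_certificates`.
#' @return named integer vector: occurrences per code among stated
#'   conditions of the training split.
#' @export
train_code_counts <- function(train_certs) {
  c(table(unlist(stated_codes(train_certs), use.names = FALSE)))
}

#' Reference top-10 frequency tables from US mortality data
#'
#' The published top-10 underlying-cause-of-death and top-10
#' stated-condition frequency tables from the US NCHS multiple-cause files
#' (2014-2017 subset, 500,000-certificate extract): code, title, count and
#' percent of total. Used as fixed inputs for coverage arithmetic and as a
#' realism reference for the generator.
#'
#' @param which `"ucod"` (most-selected underlying causes) or
#'   `"stated"` (most-stated conditions).
#' @return data.frame with `code`, `title`, `count`, `percent`.
#' @export
reference_top10 <- function(which = c("ucod", "stated")) {
  which <- match.arg(which)
  if (which == "ucod") {
    data.frame(
      code = c("I25.1", "C34.9", "J44.9", "I21.9", "G30.9",
               "F03", "I50.0", "I64", "I25.0", "J18.9"),
      title = c("Atherosclerotic heart disease",
                "Bronchus or lung, unspecified",
                "Chronic obstructive pulmonary disease, unspecified",
                "Acute myocardial infarction, unspecified",
                "Alzheimer disease, unspecified",
                "Unspecified dementia",
                "Congestive heart failure",
                "Stroke, not specified as haemorrhage or infarction",
                "Atherosclerotic cardiovascular disease, so described",
                "Pneumonia, organism unspecified"),
      count = c(26523, 26232, 21504, 20176, 19598,
                18135, 11882, 10757, 10406, 7679),
      percent = c(5.527, 5.466, 4.481, 4.204, 4.084,
                  3.779, 2.476, 2.241, 2.168, 1.600),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      code = c("I46.9", "I10", "F17.9", "I25.1", "J44.9",
               "I50.0", "F03", "A41.9", "J96.9", "J18.9"),
      title = c("Cardiac arrest, unspecified",
                "Essential (primary) hypertension",
                "Mental and behavioural disorders due to use of tobacco",
                "Atherosclerotic heart disease",
                "Chronic obstructive pulmonary disease, unspecified",
                "Congestive heart failure",
                "Unspecified dementia",
                "Sepsis, unspecified",
                "Respiratory failure, unspecified",
                "Pneumonia, unspecified"),
      count = c(62926, 62666, 54675, 52057, 50101,
                49042, 34343, 33818, 31180, 28525),
      percent = c(4.269, 4.251, 3.709, 3.531, 3.399,
                  3.327, 2.330, 2.294, 2.115, 1.935),
      stringsAsFactors = FALSE
    )
  }
}
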