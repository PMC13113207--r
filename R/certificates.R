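#' Select the ground-truth underlying cause of death
#'
#' A deterministic, simplified version of the WHO selection rules, applied in
#' a fixed cascade:
#'
#' * R1 (external-cause precedence): if any external-cause code (chapter XX)
#'   is stated anywhere, the first one in reading order is the UCOD — the
#'   external circumstance always takes precedence over the injuries it
#'   produced.
#' * R2 (originating condition): otherwise, start from the originating
#'   position — the last code of the last used Part 1 line — and walk
#'   backwards through the flattened Part 1 chain, returning the first code
#'   that is selectable, not ill-defined (chapter XVIII) and not an injury
#'   (chapter XIX).
#' * R3 (fallback): if every candidate is excluded, return the originating
#'   code regardless of flags.
#'
#' Part 2 (contributing conditions) is scanned by R1 but never reached by
#' R2/R3. The full WHO modification rules (recoding into combination
#' categories etc.) are deliberately out of scope; see the methods vignette.
#'
#' @param part1 list of character vectors: the ordered Part 1 lines.
#' @param part2 character vector of contributing-condition codes (may be
#'   empty).
#' @param codebook a [build_codebook()] result covering every stated code.
#' @return single code string.
#' @export
select_true_ucod <- function(part1, part2 = character(), codebook) {
  part1 <- part1[lengths(part1) > 0]
  chain <- unlist(part1, use.names = FALSE)
  stated <- c(chain, part2)
  if (length(stated) == 0) stop("certificate states no conditions")
  miss <- setdiff(stated, codebook$code)
  if (length(miss)) stop("code(s) not in codebook: ", paste(miss, collapse = ", "))

  ext <- codebook$is_external_cause[match(stated, codebook$code)]
  if (any(ext)) return(stated[which(ext)[1]])

  flags <- codebook[match(chain, codebook$code), ]
  ok <- flags$selectable_as_ucod & !flags$is_ill_defined & !flags$is_injury
  for (i in rev(seq_along(chain))) {
    if (ok[i]) return(chain[i])
  }
  chain[length(chain)]  # originating-condition fallback
}

#' Generate synthetic coded death certificates
#'
#' Draws certificates whose statistical shape mirrors US multiple-cause
#' mortality files at toy scale: 1-15 stated conditions spread over 1-4
#' Part 1 lines plus optional Part 2, per-code frequencies following a Zipf
#' law within the configured chapter mix, a high co-occurrence of injury and
#' external-cause codes, and a ground-truth UCOD filled in by
#' [select_true_ucod()] (so the stored label is self-consistent by
#' construction). External-cause codes are only ever placed in Part 1.
#'
#' @param codebook a `codebook`.
#' @param n number of certificates (>= 1).
#' @param config the [generator_config()] used to build the codebook.
#' @return A data.frame of class `death_certificates` with columns `cert_id`,
#'   `sex`, `age`, `part1` (list of list-of-lines), `part2` (list of
#'   character vectors) and `true_ucod`.
#' @export
generate_certificates <- function(codebook, n, config = generator_config()) {
  if (n < 1) stop("n must be >= 1")
  validate_codebook(codebook)

  # per-code sampling weight: chapter weight spread over the chapter's codes
  # with a Zipf profile inside each chapter
  w <- numeric(nrow(codebook))
  for (ch in unique(codebook$chapter)) {
    idx <- which(codebook$chapter == ch)
    cw <- config$chapter_weights[[ch]]
    if (is.null(cw) || is.na(cw)) cw <- 0
    zipf <- seq_along(idx)^(-config$imbalance_exponent)
    w[idx] <- cw * zipf / sum(zipf)
  }
  if (sum(w) <= 0) stop("chapter weights assign zero mass to every codebook chapter")
  w <- w / sum(w)
  non_ext <- !codebook$is_external_cause
  injury <- codebook$is_injury

  old <- .restore_seed()
  set.seed(config$seed + 1L)
  certs <- vector("list", n)
  any_injury <- any(injury)
  any_external <- any(codebook$is_external_cause)
  for (i in seq_len(n)) {
    n_cond <- .draw_condition_count(config$mean_conditions)
    codes <- sample(codebook$code, n_cond, replace = FALSE, prob = w)

    is_ext <- codebook$is_external_cause[match(codes, codebook$code)]
    is_inj <- codebook$is_injury[match(codes, codebook$code)]
    # realism: an external cause is normally accompanied by an injury code
    if (any(is_ext) && !any(is_inj) && any_injury &&
        stats::runif(1) < 0.8 && n_cond >= 2) {
      repl <- which(!is_ext)[1]
      codes[repl] <- sample(codebook$code[injury], 1)
    }
    # and an injury always has its external circumstance stated, so that
    # injuries are never selected as the underlying cause
    is_ext <- codebook$is_external_cause[match(codes, codebook$code)]
    is_inj <- codebook$is_injury[match(codes, codebook$code)]
    if (any(is_inj) && !any(is_ext) && any_external) {
      ext_code <- sample(codebook$code[codebook$is_external_cause], 1)
      if (length(codes) < 15L) codes <- c(codes, ext_code)
      else codes[which(is_inj)[1]] <- ext_code
    }
    codes <- codes[!duplicated(codes)]
    n_cond <- length(codes)

    has_part2 <- n_cond >= 2 && stats::runif(1) < config$part2_prob
    n_p2 <- if (has_part2) sample(1:min(3, n_cond - 1), 1) else 0L
    n_p1 <- n_cond - n_p2
    p1_codes <- codes[seq_len(n_p1)]
    p2_codes <- if (n_p2 > 0) codes[(n_p1 + 1):n_cond] else character()
    # external causes never go to Part 2 (they may be selected as UCOD)
    is_ext_p2 <- codebook$is_external_cause[match(p2_codes, codebook$code)]
    if (any(is_ext_p2)) {
      p1_codes <- c(p1_codes, p2_codes[is_ext_p2])
      p2_codes <- p2_codes[!is_ext_p2]
    }

    n_lines <- sample(seq_len(min(4, length(p1_codes))), 1)
    split_id <- sort(c(1L, sample(2:max(2, length(p1_codes)),
                                  min(n_lines - 1, max(0, length(p1_codes) - 1)))))
    line_of <- findInterval(seq_along(p1_codes), split_id)
    part1 <- unname(split(p1_codes, line_of))

    certs[[i]] <- list(
      cert_id = sprintf("cert-%06d", i),
      sex = sample(c("female", "male"), 1),
      age = max(0L, as.integer(round(stats::rnorm(1, 74, 16)))),
      part1 = part1,
      part2 = p2_codes,
      true_ucod = select_true_ucod(part1, p2_codes, codebook)
    )
  }
  .reinstate_seed(old)

  out <- data.frame(
    cert_id = vapply(certs, `[[`, "", "cert_id"),
    sex = vapply(certs, `[[`, "", "sex"),
    age = vapply(certs, `[[`, 0L, "age"),
    stringsAsFactors = FALSE
  )
  out$part1 <- lapply(certs, `[[`, "part1")
  out$part2 <- lapply(certs, `[[`, "part2")
  out$true_ucod <- vapply(certs, `[[`, "", "true_ucod")
  class(out) <- c("death_certificates", "data.frame")
  out
}

# condition count: 1 + Poisson(mean - 1), truncated to [1, 15]
.draw_condition_count <- function(mean_conditions) {
  k <- 1L + stats::rpois(1, lambda = mean_conditions - 1)
  max(1L, min(15L, k))
}

#' Count stated conditions / used Part 1 lines per certificate
#'
#' @param certs a `death_certificates` data.frame.
#' @return integer vector.
#' @export
n_conditions <- function(certs) {
  vapply(seq_len(nrow(certs)), function(i) {
    sum(lengths(certs$part1[[i]])) + length(certs$part2[[i]])
  }, integer(1))
}

#' @rdname n_conditions
#' @export
n_lines <- function(certs) {
  vapply(certs$part1, function(p1) sum(lengths(p1) > 0), integer(1))
}

#' All codes stated on a certificate
#'
#' @param certs a `death_certificates` data.frame.
#' @return list of character vectors, Part 1 reading order then Part 2.
#' @export
stated_codes <- function(certs) {
  lapply(seq_len(nrow(certs)), function(i) {
    c(unlist(certs$part1[[i]], use.names = FALSE), certs$part2[[i]])
  })
}

#' @export
print.death_certificates <- function(x, ...) {
  cat("<death_certificates> ", nrow(x), " records, ",
      length(unique(x$true_ucod)), " distinct UCOD codes\n", sep = "")
  invisible(x)
}

#' Stratified train/test/validation split
#'
#' Splits certificates into disjoint train/test/validation sets, stratified
#' by the true UCOD where class sizes permit; classes with fewer members than
#' splits fall back to random assignment (with a warning the first time).
#' Certificates stating any code in `config$ood_holdout` are removed from the
#' training split and diverted to the test split, so held-out codes have zero
#' training occurrences but remain observable at evaluation time.
#'
#' @param certs a `death_certificates` data.frame.
#' @param fractions named numeric vector `c(train=, test=, validation=)`,
#'   positive, summing to at most 1.
#' @param seed integer seed for the assignment.
#' @param ood_holdout character vector of held-out codes (defaults to none).
#' @return list with elements `train`, `test`, `validation`, each a
#'   `death_certificates` data.frame.
#' @export
split_dataset <- function(certs,
                          fractions = c(train = 0.8, test = 0.1, validation = 0.1),
                          seed = 1L, ood_holdout = character()) {
  if (nrow(certs) == 0) stop("no certificates to split")
  if (any(fractions <= 0) || sum(fractions) > 1 + 1e-9) {
    stop("fractions must be positive and sum to at most 1")
  }
  fr <- fractions[c("train", "test", "validation")]
  if (anyNA(fr)) stop("fractions must be named train/test/validation")

  old <- .restore_seed()
  set.seed(seed)
  n <- nrow(certs)
  splits <- c("train", "test", "validation", "unassigned")
  shares <- c(fr, unassigned = max(0, 1 - sum(fr)))
  # exact global counts by largest remainder
  raw <- shares * n
  counts <- floor(raw)
  rem <- order(raw - counts, decreasing = TRUE)
  short <- n - sum(counts)
  if (short > 0) counts[rem[seq_len(short)]] <- counts[rem[seq_len(short)]] + 1

  # order records class-by-class (random class order, shuffled within class),
  # then spread the split labels evenly over that ordering: every class
  # segment receives each split in close-to-ideal proportion while the global
  # counts stay exact
  if (any(table(certs$true_ucod) < 3)) {
    warning("classes with fewer than 3 members cannot be fully stratified; ",
            "their assignment is effectively random")
  }
  ord <- unlist(lapply(sample(unique(certs$true_ucod)), function(cls) {
    idx <- which(certs$true_ucod == cls)
    if (length(idx) > 1) sample(idx) else idx
  }), use.names = FALSE)
  labels <- character(n)
  assigned <- stats::setNames(numeric(4), splits)
  for (i in seq_len(n)) {
    deficit <- shares * i - assigned
    deficit[assigned >= counts] <- -Inf
    pick <- splits[which.max(deficit)]
    labels[i] <- pick
    assigned[pick] <- assigned[pick] + 1
  }
  assign_split <- rep(NA_character_, n)
  assign_split[ord] <- labels
  # OOD holdout: training certificates stating a held-out code move to test
  if (length(ood_holdout)) {
    states_holdout <- vapply(stated_codes(certs),
                             function(cs) any(cs %in% ood_holdout), logical(1))
    assign_split[states_holdout & assign_split == "train"] <- "test"
  }
  .reinstate_seed(old)

  keep <- function(lab) {
    out <- certs[assign_split == lab, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("death_certificates", "data.frame")
    out
  }
  list(train = keep("train"), test = keep("test"), validation = keep("validation"))
}

#' Write / read certificates as CSV
#'
#' Columns: cert_id, sex, age, part1_line1..part1_line4 (semicolon-joined
#' codes per line), part2 (semicolon-joined), true_ucod — a toy-scale mirror
#' of the multiple-cause layout of national mortality files.
#'
#' @param certs a `death_certificates` data.frame.
#' @param path file path.
#' @return `write_certificates` returns `path` invisibly; `read_certificates`
#'   a `death_certificates` data.frame.
#' @export
write_certificates <- function(certs, path) {
  join <- function(x) paste(x, collapse = ";")
  flat <- data.frame(cert_id = certs$cert_id, sex = certs$sex, age = certs$age,
                     stringsAsFactors = FALSE)
  for (l in 1:4) {
    flat[[paste0("part1_line", l)]] <- vapply(certs$part1, function(p1) {
      if (length(p1) >= l) join(p1[[l]]) else ""
    }, "")
  }
  flat$part2 <- vapply(certs$part2, join, "")
  flat$true_ucod <- certs$true_ucod
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_certificates
#' @export
read_certificates <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  unjoin <- function(x) if (nzchar(x)) strsplit(x, ";", fixed = TRUE)[[1]] else character()
  out <- data.frame(cert_id = flat$cert_id, sex = flat$sex,
                    age = as.integer(flat$age), stringsAsFactors = FALSE)
  out$part1 <- lapply(seq_len(nrow(flat)), function(i) {
    lines <- lapply(1:4, function(l) unjoin(flat[[paste0("part1_line", l)]][i]))
    lines[lengths(lines) > 0]
  })
  out$part2 <- lapply(flat$part2, unjoin)
  out$true_ucod <- flat$true_ucod
  class(out) <- c("death_certificates", "data.frame")
  out
}
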