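#' Render a coded certificate as its reverse-coded sentence
#'
#' Maps each stated code back to its concept title and serialises the
#' certificate as the single sentence used as classifier input:
#' `"<Sex>, <age> years: (<title>) due to (<title>) ..."` with Part 1 lines
#' flattened in line order and chained by `" due to "`. Contributing Part 2
#' conditions, when present, are appended as `"; with (<title>)"` clauses.
#'
#' @param sex "female" or "male".
#' @param age integer age in years.
#' @param part1 list of character vectors of codes (ordered Part 1 lines).
#' @param part2 character vector of codes (possibly empty).
#' @param codebook a `codebook` resolving every stated code.
#' @return a single string.
#' @export
#' @examples
#' cb <- data.frame(code = c("I21.9", "I10", "N19"),
#'                  title = c("Acute myocardial infarction", "Hypertension",
#'                            "Unspecified kidney failure"))
#' render_sentence("female", 55, list("I21.9", "I10", "N19"), character(), cb)
render_sentence <- function(sex, age, part1, part2 = character(), codebook) {
  chain <- unlist(part1, use.names = FALSE)
  all_codes <- c(chain, part2)
  idx <- match(all_codes, codebook$code)
  if (anyNA(idx)) {
    stop("code(s) missing from codebook: ",
         paste(all_codes[is.na(idx)], collapse = ", "))
  }
  title_of <- function(codes) codebook$title[match(codes, codebook$code)]
  head <- paste0(toupper(substr(sex, 1, 1)), substr(sex, 2, nchar(sex)),
                 ", ", as.integer(age), " years: ")
  body <- paste0("(", title_of(chain), ")", collapse = " due to ")
  tail <- if (length(part2)) {
    paste0(vapply(title_of(part2), function(t) paste0("; with (", t, ")"), ""),
           collapse = "")
  } else ""
  paste0(head, body, tail)
}

#' Render every certificate of a set
#'
#' @param certs a `death_certificates` data.frame.
#' @param codebook a `codebook`.
#' @return character vector of sentences, one per certificate.
#' @export
render_sentences <- function(certs, codebook) {
  vapply(seq_len(nrow(certs)), function(i) {
    render_sentence(certs$sex[i], certs$age[i], certs$part1[[i]],
                    certs$part2[[i]], codebook)
  }, "")
}

#' Recover the stated title sequence from a rendered sentence
#'
#' Parses the parenthesised titles back out of a sentence. When codebook
#' titles are unique this inverts the rendering up to code identity; with a
#' deliberate title collision the recovery is ambiguous exactly for the
#' colliding titles — the mechanism behind reverse-coding failure cases where
#' two distinct categories share one title.
#'
#' @param text a rendered sentence.
#' @return character vector of titles in reading order.
#' @export
parse_sentence_titles <- function(text) {
  m <- gregexpr("\\(([^()]*)\\)", text)[[1]]
  if (m[1] == -1) return(character())
  starts <- as.integer(m) + 1L
  lens <- attr(m, "match.length") - 2L
  substring(text, starts, starts + lens - 1L)
}

# split one whitespace-delimited chunk into tokens; leading/trailing
# punctuation become their own single-token words, interior punctuation
# (hyphens etc.) stays inside the word as extra tokens
.split_chunk <- function(chunk) {
  pieces <- regmatches(chunk, gregexpr("[a-z0-9]+|[^a-z0-9]", chunk))[[1]]
  is_word_piece <- grepl("^[a-z0-9]+$", pieces)
  n <- length(pieces)
  # word membership: the maximal run from the first to the last alphanumeric
  # piece forms one word; outer punctuation pieces are singleton words
  if (!any(is_word_piece)) {
    word_id <- seq_len(n)
  } else {
    first <- which(is_word_piece)[1]
    last <- max(which(is_word_piece))
    word_id <- integer(n)
    word_id[seq_len(n) < first] <- seq_len(sum(seq_len(n) < first))
    inner <- seq_len(n) >= first & seq_len(n) <= last
    word_id[inner] <- max(word_id, 0L) + 1L
    after <- seq_len(n) > last
    word_id[after] <- max(word_id) + seq_len(sum(after))
  }
  list(tokens = pieces, word_id = word_id)
}

#' Tokenize a sentence into words and tokens
#'
#' Lowercasing word-and-punctuation tokenizer. Tokens are maximal
#' alphanumeric runs or single punctuation characters. A "word" is a
#' whitespace-delimited chunk stripped of outer punctuation (which forms
#' punctuation words of its own); interior punctuation such as hyphens keeps
#' a word multi-token. Every token belongs to exactly one word.
#'
#' @param text input string.
#' @return data.frame with columns `token` and `word` (1-based word index).
#' @export
#' @examples
#' tokenize_text("(Hypertension) due to (Self-harm)")
tokenize_text <- function(text) {
  if (!nzchar(trimws(text))) stop("cannot tokenize empty text")
  chunks <- strsplit(trimws(tolower(text)), "\\s+")[[1]]
  tok <- character(); wid <- integer(); base <- 0L
  for (ch in chunks) {
    s <- .split_chunk(ch)
    tok <- c(tok, s$tokens)
    wid <- c(wid, base + s$word_id)
    base <- max(base + s$word_id)
  }
  data.frame(token = tok, word = wid, stringsAsFactors = FALSE)
}

#' Rebuild text from tokens
#'
#' Joins tokens with single spaces; `tokenize_text(detokenize(tokens))`
#' yields the same token sequence (whitespace normalisation aside).
#'
#' @param tokens character vector of tokens.
#' @return a single string.
#' @export
detokenize <- function(tokens) paste(tokens, collapse = " ")

#' Build a vocabulary from training sentences
#'
#' Ids follow the serialisation convention: 0 is the padding symbol, 1 the
#' unknown symbol, known tokens start at 2 in first-seen order.
#'
#' @param texts character vector of training sentences.
#' @return object of class `vocabulary`: list with `tokens` (character,
#'   including `"<pad>"` and `"<unk>"`) and the constants `pad_id = 0`,
#'   `unk_id = 1`.
#' @export
build_vocabulary <- function(texts) {
  toks <- unique(unlist(lapply(texts, function(t) tokenize_text(t)$token),
                        use.names = FALSE))
  structure(list(tokens = c("<pad>", "<unk>", toks), pad_id = 0L, unk_id = 1L),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", length(x$tokens) - 2L,
      " tokens (+ padding and unknown symbols)\n", sep = "")
  invisible(x)
}

#' Write / read a vocabulary as JSON
#'
#' A plain JSON list of token strings; positions encode the reserved ids
#' (0 = padding, 1 = unknown).
#'
#' @param vocab a `vocabulary`.
#' @param path file path.
#' @return `write_vocabulary` returns `path` invisibly; `read_vocabulary` a
#'   `vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  toks <- unlist(jsonlite::read_json(path), use.names = FALSE)
  structure(list(tokens = toks, pad_id = 0L, unk_id = 1L), class = "vocabulary")
}

#' Build sentence records: text, token ids, word map, label
#'
#' The bridge between certificates and the classifier: renders (or accepts)
#' sentences, tokenizes them against a fixed vocabulary (out-of-vocabulary
#' words map to the unknown id), and attaches the class label index.
#'
#' @param certs a `death_certificates` data.frame.
#' @param codebook a `codebook`.
#' @param vocab a [build_vocabulary()] result (built from the training
#'   split).
#' @param classes character vector fixing the class-index order
#'   (defaults to the sorted distinct UCOD codes of `certs`).
#' @return object of class `sentence_records`: list with `cert_id`, `text`,
#'   `tokens` (list of integer id vectors, 0-based convention), `word`
#'   (list of word indices per token), `label` (code) and `label_index`
#'   (integer, NA for codes outside `classes`), plus `classes` and `vocab`.
#' @export
sentence_records <- function(certs, codebook, vocab,
                             classes = sort(unique(certs$true_ucod))) {
  texts <- render_sentences(certs, codebook)
  tk <- lapply(texts, tokenize_text)
  ids <- lapply(tk, function(t) {
    i <- match(t$token, vocab$tokens) - 1L    # 0-based ids, 0=pad, 1=unk
    i[is.na(i)] <- vocab$unk_id
    i
  })
  structure(list(
    cert_id = certs$cert_id,
    text = texts,
    tokens = ids,
    word = lapply(tk, `[[`, "word"),
    label = certs$true_ucod,
    label_index = match(certs$true_ucod, classes),
    classes = classes,
    vocab = vocab
  ), class = "sentence_records")
}

#' @export
print.sentence_records <- function(x, ...) {
  cat("<sentence_records> ", length(x$text), " sentences, ",
      length(x$classes), " classes\n", sep = "")
  invisible(x)
}

#' Number of records in a sentence set
#' @param records a `sentence_records` object.
#' @return integer count.
#' @export
n_records <- function(records) length(records$text)

#' Write / read sentence records as TSV
#'
#' Columns `cert_id`, `text`, `label`; tokenization is reapplied on read, so
#' the TSV stays human-auditable.
#'
#' @param records a `sentence_records` object.
#' @param path file path.
#' @return `write_sentences` returns `path` invisibly.
#' @export
write_sentences <- function(records, path) {
  utils::write.table(
    data.frame(cert_id = records$cert_id, text = records$text,
               label = records$label, stringsAsFactors = FALSE),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
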