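# hand-built codebook with one code of every rule-relevant kind
tiny_codebook <- function() {
  cb <- data.frame(
    code = c("I21.9", "I10", "N19", "C50.9", "M72.6", "A41.9",
             "R99", "S02.1", "V03.1", "F03"),
    title = c("Acute myocardial infarction", "Hypertension",
              "Unspecified kidney failure",
              "Malignant neoplasm of breast, unspecified or malignant neoplasm, without specification of site",
              "Necrotizing fasciitis", "Sepsis, unspecified",
              "Ill-defined and unknown cause of mortality",
              "Fracture of skull", "Pedal cyclist injured in collision",
              "Unspecified dementia"),
    stringsAsFactors = FALSE
  )
  cb$chapter <- map_code_to_chapter(cb$code)
  cb$is_external_cause <- cb$chapter == "XX"
  cb$is_injury <- cb$chapter == "XIX"
  cb$is_ill_defined <- cb$chapter == "XVIII"
  cb$selectable_as_ucod <- !cb$is_injury
  class(cb) <- c("codebook", "data.frame")
  cb
}

# small generated world shared by several tests; memoised per session
generated_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_codes = 60L, seed = 42L)
      cb <- build_codebook(cfg)
      certs <- generate_certificates(cb, 800L, cfg)
      cache <<- list(cfg = cfg, codebook = cb, certs = certs)
    }
    cache
  }
})

# tiny trained model on well-separated single-condition certificates
separable_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_codes = 24L, mean_conditions = 1,
                              part2_prob = 0, seed = 5L)
      cb <- build_codebook(cfg)
      certs <- generate_certificates(cb, 600L, cfg)
      sp <- suppressWarnings(split_dataset(certs, seed = 6L))
      vocab <- build_vocabulary(render_sentences(sp$train, cb))
      classes <- sort(unique(certs$true_ucod))
      train <- sentence_records(sp$train, cb, vocab, classes)
      test <- sentence_records(sp$test, cb, vocab, classes)
      fit <- train_with_checkpoints(train, d = 16L, hidden = 8L,
                                    epochs = 20L, K = 5L, seed = 7L)
      cache <<- list(codebook = cb, splits = sp, train = train, test = test,
                     fit = fit, classes = classes)
    }
    cache
  }
})

# naive per-cell double-loop oracle for the across-checkpoint gradient
# variance score (population variance, denominator K)
naive_vog <- function(checkpoints, tokens, p, layer = "softmax") {
  grads <- lapply(checkpoints$models, token_gradients, tokens = tokens,
                  p = p, layer = layer)
  K <- length(grads)
  nr <- nrow(grads[[1]]); nc <- ncol(grads[[1]])
  total <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      cell <- vapply(grads, function(g) g[i, j], numeric(1))
      mu <- sum(cell) / K
      total <- total + sum((cell - mu)^2) / K
    }
  }
  total / (nr * nc)
}

# single-record prediction frame from bare confidences/correctness
pf_from <- function(confidence, correct) {
  data.frame(id = sprintf("p%d", seq_along(confidence)),
             predicted = ifelse(correct, 1L, 2L), label = 1L,
             confidence = confidence, correct = correct,
             stringsAsFactors = FALSE)
}
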