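#' A small differentiable text classifier
#'
#' Architecture: token embedding table -> mean pooling over non-padding
#' tokens -> optional tanh hidden layer -> affine map to class logits.
#' Deliberately tiny: calibration, Variance-of-Gradients and Integrated
#' Gradients are architecture-agnostic, and the mean-pool design admits
#' closed-form oracles for the gradient of any class logit with respect to
#' each token embedding. With `hidden = 0` the logit is exactly linear in the
#' embedded input; with `hidden > 0` the model is smooth but nonlinear, which
#' is what the attribution-completeness checks exercise.
#'
#' @name text_classifier
#' @keywords internal
NULL

# parameter container; E rows are indexed by token id + 1 (id 0 = padding)
.new_classifier <- function(E, W1, b1, W2, b2, config, classes, vocab_size) {
  structure(list(E = E, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 config = config, classes = classes, vocab_size = vocab_size),
            class = "text_classifier")
}

#' @export
print.text_classifier <- function(x, ...) {
  cat("<text_classifier> d=", ncol(x$E), ", hidden=",
      if (is.null(x$W1)) 0 else ncol(x$W1), ", k=", length(x$classes),
      ", vocab=", x$vocab_size, "\n", sep = "")
  invisible(x)
}

# dense pooling matrix: row i holds 1/L_i at the embedding row of each
# non-padding token of record i
.pooling_matrix <- function(token_lists, vocab_size) {
  n <- length(token_lists)
  P <- matrix(0, n, vocab_size)
  for (i in seq_len(n)) {
    ids <- token_lists[[i]]
    ids <- ids[ids != 0L]
    if (length(ids) == 0L) stop("record ", i, " contains only padding tokens")
    tab <- table(ids)
    P[i, as.integer(names(tab)) + 1L] <- as.numeric(tab) / length(ids)
  }
  P
}

.forward <- function(model, X) {
  if (is.null(model$W1)) {
    list(logits = sweep(X %*% model$W2, 2, model$b2, `+`), hidden = NULL)
  } else {
    H <- tanh(sweep(X %*% model$W1, 2, model$b1, `+`))
    list(logits = sweep(H %*% model$W2, 2, model$b2, `+`), hidden = H)
  }
}

#' Train the classifier, capturing checkpoints
#'
#' Cross-entropy training with the Adam optimizer on shuffled minibatches.
#' `K` parameter snapshots are captured at evenly spaced epochs
#' (`floor(j * epochs / K)` for `j = 1..K`), the last one being the final
#' model. Fully deterministic for a given seed.
#'
#' @param records a [sentence_records()] object with at least two classes
#'   present.
#' @param d embedding width.
#' @param hidden hidden-layer width (0 disables the tanh layer and makes the
#'   logits linear in the embedded input).
#' @param epochs training epochs (>= K).
#' @param K number of checkpoints (>= 2 for downstream variance scoring).
#' @param learning_rate Adam step size.
#' @param weight_decay decoupled L2 weight decay per step (0 disables).
#'   A small positive value bounds the growth of logit margins so the
#'   parameters genuinely settle, which matters when later snapshots are
#'   meant to reflect a converged model.
#' @param batch_size minibatch size.
#' @param embed_init_sd standard deviation of the random embedding
#'   initialisation. Embeddings of words never seen in training keep their
#'   initial vectors, so this scale controls how far out-of-vocabulary
#'   material displaces the pooled representation from the trained manifold.
#' @param seed integer seed for initialisation and shuffling.
#' @return list with `model` (the final `text_classifier`) and `checkpoints`
#'   (a `checkpoint_set`: list of models plus their epoch tags).
#' @export
train_with_checkpoints <- function(records, d = 32L, hidden = 0L,
                                   epochs = 30L, K = 5L,
                                   learning_rate = 0.05, weight_decay = 0,
                                   batch_size = 64L,
                                   embed_init_sd = 1.0, seed = 1L) {
  if (length(unique(records$label_index)) < 2) {
    stop("training data must contain at least two classes")
  }
  if (anyNA(records$label_index)) stop("records with labels outside the class set")
  if (epochs < K) stop("need epochs >= K to place K distinct checkpoints")
  k <- length(records$classes)
  vocab_size <- length(records$vocab$tokens)
  n <- n_records(records)

  P <- .pooling_matrix(records$tokens, vocab_size)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), records$label_index)] <- 1

  old <- .restore_seed()
  set.seed(seed)
  E <- matrix(stats::rnorm(vocab_size * d, sd = embed_init_sd), vocab_size, d)
  E[1, ] <- 0   # padding embedding stays zero
  if (hidden > 0) {
    W1 <- matrix(stats::rnorm(d * hidden, sd = sqrt(1 / d)), d, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden * k, sd = sqrt(1 / hidden)), hidden, k)
  } else {
    W1 <- NULL; b1 <- NULL
    W2 <- matrix(stats::rnorm(d * k, sd = sqrt(1 / d)), d, k)
  }
  b2 <- numeric(k)

  params <- list(E = E, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(p) if (is.null(p)) NULL else p * 0)
  vel <- mom
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

  checkpoint_epochs <- floor(seq_len(K) * epochs / K)
  snapshots <- vector("list", K)
  cfg <- list(d = d, hidden = hidden, epochs = epochs, K = K,
              learning_rate = learning_rate, weight_decay = weight_decay,
              batch_size = batch_size, embed_init_sd = embed_init_sd,
              seed = seed)

  for (epoch in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Pb <- P[idx, , drop = FALSE]
      Xb <- Pb %*% params$E
      fw <- .forward(.new_classifier(params$E, params$W1, params$b1,
                                     params$W2, params$b2, cfg,
                                     records$classes, vocab_size), Xb)
      prob <- softmax(fw$logits)
      dlog <- (prob - Y[idx, , drop = FALSE]) / length(idx)

      if (hidden > 0) {
        H <- fw$hidden
        g_W2 <- t(H) %*% dlog
        g_b2 <- colSums(dlog)
        dH <- (dlog %*% t(params$W2)) * (1 - H^2)
        g_W1 <- t(Xb) %*% dH
        g_b1 <- colSums(dH)
        dX <- dH %*% t(params$W1)
      } else {
        g_W2 <- t(Xb) %*% dlog
        g_b2 <- colSums(dlog)
        dX <- dlog %*% t(params$W2)
        g_W1 <- NULL; g_b1 <- NULL
      }
      g_E <- t(Pb) %*% dX
      grads <- list(E = g_E, W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2)

      t_step <- t_step + 1
      for (nm in names(params)) {
        if (is.null(params[[nm]])) next
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^t_step)
        vhat <- vel[[nm]] / (1 - beta2^t_step)
        params[[nm]] <- params[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
        if (weight_decay > 0 && nm != "b2" && nm != "b1") {
          params[[nm]] <- params[[nm]] * (1 - learning_rate * weight_decay)
        }
      }
      params$E[1, ] <- 0   # keep the padding embedding pinned at zero
    }
    hit <- which(checkpoint_epochs == epoch)
    for (j in hit) {
      snapshots[[j]] <- .new_classifier(params$E, params$W1, params$b1,
                                        params$W2, params$b2, cfg,
                                        records$classes, vocab_size)
    }
  }
  .reinstate_seed(old)

  cps <- structure(list(models = snapshots, epochs = checkpoint_epochs),
                   class = "checkpoint_set")
  list(model = snapshots[[K]], checkpoints = cps)
}

#' @export
print.checkpoint_set <- function(x, ...) {
  cat("<checkpoint_set> ", length(x$models), " snapshots at epochs ",
      paste(x$epochs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Logits for sentence records
#'
#' @param model a `text_classifier`.
#' @param records a `sentence_records` object (or a single integer token-id
#'   vector).
#' @return numeric matrix (n x k) of pre-softmax logits.
#' @export
predict_logits <- function(model, records) {
  token_lists <- if (inherits(records, "sentence_records")) records$tokens
                 else list(as.integer(records))
  if (any(vapply(token_lists, length, 1L) == 0L)) stop("empty token list")
  bad <- vapply(token_lists, function(t) any(t < 0 | t >= model$vocab_size),
                logical(1))
  if (any(bad)) stop("token ids outside the model vocabulary")
  P <- .pooling_matrix(token_lists, model$vocab_size)
  .forward(model, P %*% model$E)$logits
}

#' Predictions for sentence records as a prediction set
#'
#' @param model a `text_classifier`.
#' @param records a `sentence_records` object.
#' @return a [prediction_set()] with the records' label indices as labels.
#' @export
predict_set <- function(model, records) {
  z <- predict_logits(model, records)
  prediction_set(z, records$label_index,
                 provenance = list(source = "model"),
                 ids = records$cert_id)
}

#' Gradient of a class output with respect to token embeddings
#'
#' Returns the matrix `S` with `S[i, j] = d F_p / d e_ij`, the derivative of
#' the class-`p` output with respect to component `j` of token `i`'s
#' embedding vector, at the record's current embedded input. `layer`
#' selects the output: the pre-softmax logit (default) or the post-softmax
#' activation (the class probability, whose gradient carries the
#' `p * (1 - p)` confidence damping). Padding positions are excluded. Under
#' mean pooling every non-padding token shares the pooled gradient scaled by
#' `1 / L`; for the linear architecture at the logit layer this is exactly
#' `W2[, p] / L`.
#'
#' @param model a `text_classifier` (any snapshot).
#' @param tokens integer token-id vector for one record (0 = padding).
#' @param p class index in `1..k`.
#' @param layer `"logit"` or `"softmax"`.
#' @return numeric matrix (non-padding tokens x d).
#' @export
token_gradients <- function(model, tokens, p, layer = c("logit", "softmax")) {
  layer <- match.arg(layer)
  k <- length(model$classes)
  if (p < 1 || p > k) stop("class index p out of range")
  ids <- as.integer(tokens)
  ids <- ids[ids != 0L]
  if (length(ids) == 0L) stop("record contains only padding tokens")
  L <- length(ids)
  xbar <- colMeans(model$E[ids + 1L, , drop = FALSE])
  g <- if (layer == "logit") {
    .pooled_gradient(model, xbar, p)
  } else {
    .pooled_softmax_gradient(model, xbar, p)
  }
  matrix(rep(g / L, each = L), nrow = L)
}

# d logit_p / d pooled-embedding at pooled input xbar
.pooled_gradient <- function(model, xbar, p) {
  if (is.null(model$W1)) {
    model$W2[, p]
  } else {
    h <- tanh(as.numeric(xbar %*% model$W1) + model$b1)
    as.numeric(model$W1 %*% ((1 - h^2) * model$W2[, p]))
  }
}

# d softmax_p / d pooled-embedding: prob_p * (g_p - sum_c prob_c g_c)
# with g_c the logit gradients
.pooled_softmax_gradient <- function(model, xbar, p) {
  if (is.null(model$W1)) {
    Gz <- model$W2                                   # d x k logit gradients
    z <- as.numeric(xbar %*% model$W2) + model$b2
  } else {
    h <- tanh(as.numeric(xbar %*% model$W1) + model$b1)
    Gz <- model$W1 %*% ((1 - h^2) * model$W2)
    z <- as.numeric(h %*% model$W2) + model$b2
  }
  prob <- exp(z - max(z)); prob <- prob / sum(prob)
  prob[p] * (Gz[, p] - as.numeric(Gz %*% prob))
}

#' Save / load a model checkpoint directory
#'
#' Writes every snapshot plus a JSON manifest (config, epochs, content
#' hashes) to a directory.
#'
#' @param checkpoints a `checkpoint_set`.
#' @param dir target directory (created if needed).
#' @return `save_checkpoints` returns `dir` invisibly; `load_checkpoints` a
#'   `checkpoint_set`.
#' @export
save_checkpoints <- function(checkpoints, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(checkpoints$models))
  for (i in seq_along(checkpoints$models)) {
    files[i] <- file.path(dir, sprintf("checkpoint-%03d.rds", i))
    saveRDS(checkpoints$models[[i]], files[i])
  }
  manifest <- list(
    config = checkpoints$models[[1]]$config,
    epochs = checkpoints$epochs,
    files = basename(files),
    hashes = vapply(files, function(f) unname(tools::md5sum(f)), "")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_checkpoints
#' @export
load_checkpoints <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  models <- lapply(manifest$files, function(f) readRDS(file.path(dir, f)))
  structure(list(models = models, epochs = as.integer(manifest$epochs)),
            class = "checkpoint_set")
}
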