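#' Pipeline configuration
#'
#' One nested list with a block per stage, so every analysis decision that
#' the underlying method leaves open (bin count, difficulty-score mode,
#' attribution baseline, fitting objective, ...) is a one-line change in a
#' config file. Defaults are the desk-scale study conditions: 5,000
#' certificates over a 60-code ontology (about 50 selectable target
#' classes), an 80/10/10 stratified split, and a 5-checkpoint training run.
#'
#' @param generator list block: `n_codes`, `imbalance_exponent`,
#'   `mean_conditions`, `part2_prob`, `ood_holdout_n` (codes held out of
#'   training), `title_collision`.
#' @param data list block: `n_certificates`, `fractions`.
#' @param model list block: `d`, `hidden`, `epochs`, `K`, `learning_rate`,
#'   `batch_size`.
#' @param calibration list block: `bins`, `objective`.
#' @param vog list block: `mode`, `layer`, `flag_quantile`, `class_of`.
#' @param saliency list block: `steps`, `method`, `baseline`, `n_correct`,
#'   `n_incorrect`.
#' @param report list block: `top_k`.
#' @param seed global seed propagated to every stochastic stage.
#' @return object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(generator = list(), data = list(), model = list(),
                            calibration = list(), vog = list(),
                            saliency = list(), report = list(), seed = 1L) {
  merge_block <- function(defaults, given) {
    defaults[names(given)] <- given
    defaults
  }
  cfg <- list(
    generator = merge_block(list(n_codes = 60L, imbalance_exponent = 1.0,
                                 mean_conditions = 3, part2_prob = 0.25,
                                 ood_holdout_n = 3L, title_collision = FALSE),
                            generator),
    data = merge_block(list(n_certificates = 5000L,
                            fractions = c(train = 0.8, test = 0.1,
                                          validation = 0.1)),
                       data),
    model = merge_block(list(d = 32L, hidden = 256L, epochs = 40L, K = 5L,
                             learning_rate = 0.05, batch_size = 64L),
                        model),
    calibration = merge_block(list(bins = 10L, objective = "nll"), calibration),
    vog = merge_block(list(mode = "checkpoint", layer = "softmax",
                           flag_quantile = 0.95, class_of = "true"), vog),
    saliency = merge_block(list(steps = 50L, method = "gauss_legendre",
                                baseline = "padding", n_correct = 3L,
                                n_incorrect = 3L),
                           saliency),
    report = merge_block(list(top_k = 10L), report),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg a `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$data$fractions <- unlist(raw$data$fractions)
  do.call(pipeline_config, raw[intersect(names(raw),
    c("generator", "data", "model", "calibration", "vog", "saliency",
      "report", "seed"))])
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$data$fractions <- as.list(out$data$fractions)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full interpretability pipeline
#'
#' Generate -> reverse-code -> train -> calibrate -> difficulty-score ->
#' attribute -> report, writing every intermediate and summary to a run
#' directory along with a manifest (config, per-stage status, content
#' hashes). Deterministic and idempotent for a fixed config: running twice
#' produces identical manifests.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param out_dir output directory (created; existing files overwritten).
#' @return invisibly, a list with the run directory, the manifest, and the
#'   in-memory stage results (`codebook`, `splits`, `model`, `calibration`,
#'   `vog`, `saliency`, `reports`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("mortexplain-run-")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      status[[name]] <<- paste("failed:", conditionMessage(e))
      manifest <- list(config = unclass(config), stages = status)
      jsonlite::write_json(manifest, file.path(out_dir, "FAILED.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    status[[name]] <<- "ok"
    res
  }

  seed <- config$seed
  gcfg <- stage("generate", {
    g <- config$generator
    generator_config(n_codes = g$n_codes,
                     imbalance_exponent = g$imbalance_exponent,
                     mean_conditions = g$mean_conditions,
                     part2_prob = g$part2_prob,
                     title_collision = g$title_collision,
                     seed = seed)
  })
  codebook <- stage("codebook", build_codebook(gcfg))
  write_codebook(codebook, file.path(out_dir, "codebook.json"))

  certs <- stage("certificates",
                 generate_certificates(codebook, config$data$n_certificates, gcfg))
  write_certificates(certs, file.path(out_dir, "certificates.csv"))

  splits <- stage("split", {
    # hold the rarest stated (non-external) codes out of training for the
    # OOD analysis: certificates stating them divert to the test split, so
    # the codes have zero training occurrences but stay observable
    holdout <- character()
    if (config$generator$ood_holdout_n > 0) {
      cnt <- sort(train_code_counts(certs))
      cand <- names(cnt)[!codebook$is_external_cause[match(names(cnt), codebook$code)]]
      holdout <- utils::head(cand, config$generator$ood_holdout_n)
    }
    suppressWarnings(split_dataset(certs, config$data$fractions,
                                   seed = seed + 17L, ood_holdout = holdout))
  })
  for (nm in names(splits)) {
    write_certificates(splits[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }

  sentences <- stage("reverse_coding", {
    vocab <- build_vocabulary(render_sentences(splits$train, codebook))
    classes <- sort(unique(certs$true_ucod))
    lapply(splits, sentence_records, codebook = codebook, vocab = vocab,
           classes = classes)
  })
  write_vocabulary(sentences$train$vocab, file.path(out_dir, "vocabulary.json"))
  for (nm in names(sentences)) {
    write_sentences(sentences[[nm]], file.path(out_dir, paste0("sentences-", nm, ".tsv")))
  }

  trained <- stage("train", {
    m <- config$model
    train_with_checkpoints(sentences$train, d = m$d, hidden = m$hidden,
                           epochs = m$epochs, K = m$K,
                           learning_rate = m$learning_rate,
                           batch_size = m$batch_size, seed = seed + 29L)
  })
  save_checkpoints(trained$checkpoints, file.path(out_dir, "checkpoints"))

  preds <- stage("predict", {
    ps <- lapply(sentences[c("test", "validation")], predict_set,
                 model = trained$model)
    write_prediction_set(ps$test, file.path(out_dir, "predictions-test.jsonl"))
    write_prediction_set(ps$validation, file.path(out_dir, "predictions-validation.jsonl"))
    ps
  })

  calib <- stage("calibrate", {
    cal <- calibrate_predictions(preds$test, preds$validation,
                                 M = config$calibration$bins,
                                 objective = config$calibration$objective)
    jsonlite::write_json(
      list(temperature = cal$temperature$T,
           objective = cal$temperature$objective,
           bound_hit = cal$temperature$bound_hit,
           ece_before = cal$before$ece, mce_before = cal$before$mce,
           ece_after = cal$after$ece, mce_after = cal$after$mce),
      file.path(out_dir, "calibration.json"), auto_unbox = TRUE, pretty = TRUE)
    utils::write.csv(cal$reliability, file.path(out_dir, "reliability.csv"),
                     row.names = FALSE)
    cal
  })

  if (config$model$K < 2) {
    stage("vog", stop("difficulty scoring needs at least 2 checkpoints"))
  }
  vog <- stage("vog", {
    vr <- vog_records(trained$checkpoints, sentences$test,
                      class_of = config$vog$class_of, mode = config$vog$mode,
                      layer = config$vog$layer)
    vr$n_conditions <- n_conditions(splits$test)
    vr$n_lines <- n_lines(splits$test)
    vr <- normalize_vog(vr)
    tcounts <- train_code_counts(splits$train)
    stated <- stated_codes(splits$test)
    ranked <- rank_and_flag(vr, stated, tcounts, config$vog$flag_quantile)
    freq <- vog_frequency_analysis(vr, stated, tcounts,
                                   ranges = .desk_scale_ranges(tcounts))
    by_class <- split(seq_len(nrow(vr)), vr$label_index)
    cls_ok <- lengths(by_class) > 0
    class_stats <- data.frame(
      label_index = as.integer(names(by_class)),
      mean_vog = vapply(by_class, function(i) mean(vr$global_norm_vog[i]), 0),
      mean_conditions = vapply(by_class, function(i) mean(vr$n_conditions[i]), 0),
      mean_lines = vapply(by_class, function(i) mean(vr$n_lines[i]), 0))
    cors <- tryCatch(
      difficulty_correlations(class_stats$mean_vog, class_stats$mean_conditions,
                              class_stats$mean_lines),
      error = function(e) NULL)
    utils::write.csv(ranked, file.path(out_dir, "vog-records.csv"), row.names = FALSE)
    freq_json <- freq$table
    freq_json$hi <- as.character(freq_json$hi)   # JSON cannot carry Inf
    jsonlite::write_json(list(frequency_table = freq_json,
                              log2_trend = freq$log2_trend,
                              correlations = cors),
                         file.path(out_dir, "vog-analysis.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(records = ranked, frequency = freq, class_stats = class_stats,
         correlations = cors)
  })

  sal <- stage("saliency", {
    s <- config$saliency
    render_saliency_report(trained$model, sentences$test, codebook,
                           n_correct = s$n_correct, n_incorrect = s$n_incorrect,
                           out_html = file.path(out_dir, "saliency.html"),
                           out_tsv = file.path(out_dir, "saliency.tsv"),
                           steps = s$steps, method = s$method,
                           baseline = s$baseline)
  })

  reports <- stage("report", {
    pf <- prediction_frame(preds$test, temperature = calib$temperature$T)
    classes <- sentences$test$classes
    chap <- chapter_accuracy_table(pf, splits$test, classes)
    topk_target <- top_k_frequency_table(certs$true_ucod, config$report$top_k,
                                         codebook)
    topk_stated <- top_k_frequency_table(
      unlist(stated_codes(certs), use.names = FALSE), config$report$top_k,
      codebook)
    tcounts_class <- c(table(splits$train$true_ucod))
    conf_chapter <- confidence_group_stats(pf, splits$test$true_ucod, "chapter")
    conf_class <- confidence_group_stats(pf, splits$test$true_ucod, "class",
                                         train_counts = tcounts_class)
    utils::write.csv(chap, file.path(out_dir, "chapter-table.csv"), row.names = FALSE)
    utils::write.csv(topk_target, file.path(out_dir, "top-ucod.csv"), row.names = FALSE)
    utils::write.csv(topk_stated, file.path(out_dir, "top-stated.csv"), row.names = FALSE)
    utils::write.csv(conf_chapter, file.path(out_dir, "confidence-by-chapter.csv"),
                     row.names = FALSE)
    utils::write.csv(conf_class, file.path(out_dir, "confidence-by-class.csv"),
                     row.names = FALSE)
    list(chapter = chap, top_ucod = topk_target, top_stated = topk_stated,
         confidence_chapter = conf_chapter, confidence_class = conf_class,
         accuracy = mean(pf$correct))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("mortexplain")),
    config = unclass(config),
    stages = status,
    outputs = {
      fs <- setdiff(list.files(out_dir), c("manifest.json", "checkpoints"))
      stats::setNames(
        vapply(file.path(out_dir, fs), function(f) unname(tools::md5sum(f)), ""),
        fs)
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dir = out_dir, manifest = manifest, codebook = codebook,
                 splits = splits, sentences = sentences, model = trained,
                 predictions = preds, calibration = calib, vog = vog,
                 saliency = sal, reports = reports))
}

# frequency bands rescaled to toy-sized training sets: never seen, 1-2,
# then powers-of-ten style bands up to the observed maximum
.desk_scale_ranges <- function(train_counts) {
  mx <- max(train_counts)
  if (mx > 20000) return(default_frequency_ranges())
  his <- c(0, 2, 10, 50, 200, Inf)
  data.frame(lo = c(0, 1, 3, 11, 51, 201), hi = his)
}
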