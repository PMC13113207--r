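#' Generator configuration
#'
#' Bundles every knob of the synthetic certificate world: how many codes the
#' ontology holds, how stated conditions are spread over ICD-10 chapters, how
#' long-tailed the per-code frequencies are, which codes are withheld from
#' training (the out-of-distribution holdout), and the reproducibility seed.
#' The configuration defines the ground-truth joint distribution that every
#' downstream calibration and difficulty analysis is evaluated against.
#'
#' @param n_codes number of distinct codes in the codebook.
#' @param chapter_weights named numeric vector (roman-numeral chapter ids) of
#'   sampling weights for stated conditions; normalised to sum to 1. The
#'   default is proportional to the chapter mix of stated conditions observed
#'   in US multiple-cause mortality files (2014-2017 subset), with the
#'   administrative chapters XXI/XXII at zero.
#' @param imbalance_exponent Zipf exponent for within-chapter code
#'   frequencies; 0 gives uniform use, larger values a longer tail.
#' @param ood_holdout character vector of codes to exclude from the training
#'   split (certificates stating them are diverted to the test split).
#' @param title_collision if TRUE, one pair of distinct codes deliberately
#'   shares a title, emulating the duplicate-title ambiguity of real ICD-10.
#' @param mean_conditions expected number of stated conditions per
#'   certificate (truncated to the 1-15 range seen on real certificates).
#' @param part2_prob probability that a certificate carries contributing
#'   (Part 2) conditions.
#' @param seed integer seed controlling all generator randomness.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_codes = 300L,
                             chapter_weights = default_chapter_weights(),
                             imbalance_exponent = 1.0,
                             ood_holdout = character(),
                             title_collision = FALSE,
                             mean_conditions = 3,
                             part2_prob = 0.25,
                             seed = 1L) {
  if (!is.numeric(chapter_weights) || any(chapter_weights < 0) ||
      !all(names(chapter_weights) %in% icd10_chapters()$chapter) ||
      sum(chapter_weights) <= 0) {
    stop("invalid chapter weights: need non-negative weights named by chapter, summing > 0")
  }
  if (imbalance_exponent < 0) stop("imbalance_exponent must be >= 0")
  if (mean_conditions < 1 || mean_conditions > 15) {
    stop("mean_conditions must lie in [1, 15]")
  }
  structure(list(
    n_codes = as.integer(n_codes),
    chapter_weights = chapter_weights / sum(chapter_weights),
    imbalance_exponent = imbalance_exponent,
    ood_holdout = as.character(ood_holdout),
    title_collision = isTRUE(title_collision),
    mean_conditions = mean_conditions,
    part2_prob = part2_prob,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default chapter weights for stated conditions
#'
#' Proportional to the published chapter mix of input conditions in US
#' multiple-cause-of-death files (2014-2017 subset); chapters XXI and XXII do
#' not occur on certificates and get weight zero.
#'
#' @return named numeric vector over the 22 chapters, summing to 1.
#' @export
default_chapter_weights <- function() {
  w <- c(I = 2.521, II = 22.118, III = 0.857, IV = 5.857, V = 7.892,
         VI = 3.908, VII = 0.030, VIII = 0.009, IX = 31.116, X = 11.735,
         XI = 3.271, XII = 0.289, XIII = 0.835, XIV = 4.472, XV = 0.044,
         XVI = 0.378, XVII = 0.212, XVIII = 6.238, XIX = 5.935, XX = 3.579,
         XXI = 0, XXII = 0)
  w / sum(w)
}

# chapter-specific condition phrase pools used to manufacture unique titles
.chapter_phrases <- function() {
  list(
    I = c("septicaemia", "tuberculosis of lung", "viral hepatitis",
          "bacterial infection", "intestinal infection", "meningococcal infection",
          "candidiasis", "herpesviral infection", "mycosis", "protozoal disease"),
    II = c("malignant neoplasm of bronchus or lung", "malignant neoplasm of breast",
           "malignant neoplasm of prostate", "malignant neoplasm of colon",
           "malignant neoplasm of pancreas", "malignant neoplasm of stomach",
           "malignant neoplasm of liver", "lymphoid leukaemia",
           "multiple myeloma", "malignant melanoma of skin"),
    III = c("anaemia", "aplastic anaemia", "coagulation defect",
            "thrombocytopenia", "immunodeficiency", "sickle-cell disorder",
            "agranulocytosis", "polycythaemia"),
    IV = c("diabetes mellitus", "malnutrition", "obesity", "thyrotoxicosis",
           "hypothyroidism", "disorder of lipoprotein metabolism",
           "volume depletion", "cystic fibrosis", "amyloidosis", "gout"),
    V = c("dementia", "vascular dementia", "mental disorder due to alcohol use",
          "mental disorder due to tobacco use", "mental disorder due to opioid use",
          "schizophrenia", "depressive episode", "delirium", "anxiety disorder"),
    VI = c("alzheimer disease", "parkinson disease", "epilepsy",
           "motor neuron disease", "multiple sclerosis", "hydrocephalus",
           "encephalopathy", "polyneuropathy", "migraine", "myasthenia gravis"),
    VII = c("glaucoma", "cataract", "retinal detachment", "keratitis",
            "disorder of optic nerve", "blindness"),
    VIII = c("otitis media", "disorder of vestibular function", "hearing loss",
             "mastoiditis", "cholesteatoma of middle ear"),
    IX = c("acute myocardial infarction", "atherosclerotic heart disease",
           "congestive heart failure", "cardiac arrest", "atrial fibrillation",
           "hypertensive heart disease", "essential hypertension",
           "cerebral infarction", "intracerebral haemorrhage", "stroke",
           "aortic aneurysm", "cardiomyopathy", "pulmonary embolism",
           "peripheral vascular disease"),
    X = c("pneumonia", "chronic obstructive pulmonary disease", "asthma",
          "respiratory failure", "pulmonary oedema", "influenza",
          "emphysema", "bronchiectasis", "pneumonitis due to solids and liquids",
          "interstitial pulmonary disease", "pleural effusion"),
    XI = c("gastrointestinal haemorrhage", "alcoholic liver disease",
           "fibrosis and cirrhosis of liver", "ileus", "peritonitis",
           "acute pancreatitis", "gastric ulcer", "diverticular disease of intestine",
           "cholelithiasis", "necrotizing fasciitis of abdominal wall"),
    XII = c("decubitus ulcer", "cellulitis", "pemphigus",
            "dermatitis", "psoriasis", "ulcer of lower limb"),
    XIII = c("rheumatoid arthritis", "systemic sclerosis", "osteomyelitis",
             "systemic lupus erythematosus", "osteoporosis with pathological fracture",
             "polymyalgia rheumatica", "dermatopolymyositis", "spondylosis"),
    XIV = c("kidney failure", "chronic kidney disease", "acute kidney failure",
            "urinary tract infection", "hyperplasia of prostate",
            "glomerular disease", "calculus of kidney", "cystitis"),
    XV = c("eclampsia in pregnancy", "obstetric embolism", "postpartum haemorrhage",
           "pre-eclampsia", "obstructed labour", "puerperal sepsis"),
    XVI = c("extreme immaturity of newborn", "birth asphyxia",
            "respiratory distress of newborn", "bacterial sepsis of newborn",
            "neonatal aspiration syndrome", "intrauterine hypoxia"),
    XVII = c("congenital malformation of heart", "spina bifida",
             "down syndrome", "congenital hydrocephalus",
             "congenital malformation of kidney", "edwards syndrome"),
    XVIII = c("senility", "cachexia", "sudden death, cause unknown",
              "unattended death", "abnormal weight loss", "febrile convulsions",
              "ill-defined and unknown cause of mortality", "dysphagia"),
    XIX = c("fracture of femur", "fracture of skull", "intracranial injury",
            "injury of thorax", "poisoning by narcotics", "poisoning by psychodysleptics",
            "traumatic subdural haemorrhage", "burn of trunk",
            "foreign body in respiratory tract", "multiple injuries"),
    XX = c("fall on same level", "fall from height", "pedestrian injured in transport accident",
           "car occupant injured in traffic accident", "accidental poisoning by drugs",
           "intentional self-poisoning", "intentional self-harm by firearm",
           "assault by sharp object", "accidental drowning", "exposure to smoke and fire",
           "motorcycle rider injured in traffic accident"),
    XXI = c("contact with health services"),
    XXII = c("emergency use condition")
  )
}

.title_modifiers <- c("", "Acute", "Chronic", "Recurrent", "Secondary",
                      "Subacute", "Progressive")
.title_suffixes <- c("", ", unspecified", ", so described", ", severe",
                     ", with complications")

# draw `n` unique (code, title) pairs inside one chapter
.generate_chapter_entries <- function(chapter, n, tab) {
  row <- tab[tab$chapter == chapter, ]
  lo <- .category_key(row$from); hi <- .category_key(row$to)
  keys <- lo:hi
  # candidate codes: every category plus its .0/.1/.9 subdivisions
  cats <- paste0(LETTERS[keys %/% 100 + 1L],
                 formatC(keys %% 100, width = 2, flag = "0"))
  cand <- c(cats, paste0(rep(cats, each = 3), ".", c("0", "1", "9")))
  if (n > length(cand)) stop("chapter ", chapter, " cannot host ", n, " codes")
  codes <- sample(cand, n)

  base <- .chapter_phrases()[[chapter]]
  grid <- expand.grid(m = .title_modifiers, b = base, s = .title_suffixes,
                      stringsAsFactors = FALSE)
  titles_pool <- trimws(paste(grid$m, grid$b, sep = " "))
  titles_pool <- paste0(toupper(substr(titles_pool, 1, 1)),
                        substr(titles_pool, 2, nchar(titles_pool)), grid$s)
  titles_pool <- unique(titles_pool)
  if (n > length(titles_pool)) stop("not enough distinct titles for chapter ", chapter)
  data.frame(code = codes, title = sample(titles_pool, n),
             chapter = chapter, stringsAsFactors = FALSE)
}

#' Build a synthetic codebook
#'
#' Creates an ICD-10-like ontology: codes allocated to chapters according to
#' the configured chapter weights, each with a unique human-readable title and
#' the selection flags that drive underlying-cause-of-death rules
#' (external cause, injury, ill-defined, selectable). Deterministic for a
#' given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return A data.frame of class `codebook` with columns `code`, `title`,
#'   `chapter`, `is_external_cause`, `is_injury`, `is_ill_defined`,
#'   `selectable_as_ucod`.
#' @export
build_codebook <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  w <- config$chapter_weights
  pos <- names(w)[w > 0]
  if (config$n_codes < length(pos)) {
    stop("n_codes must be at least the number of positively weighted chapters")
  }
  # largest-remainder allocation of codes to chapters, >= 1 per active chapter
  raw <- unname(w[pos]) * config$n_codes
  alloc <- pmax(1L, floor(raw))
  while (sum(alloc) > config$n_codes) {
    over <- alloc - raw
    over[alloc <= 1L] <- -Inf
    if (all(!is.finite(over))) break
    i <- which.max(over)
    alloc[i] <- alloc[i] - 1L
  }
  while (sum(alloc) < config$n_codes) {
    i <- which.min((alloc - raw) / pmax(raw, 1e-9))
    alloc[i] <- alloc[i] + 1L
  }
  names(alloc) <- pos

  tab <- icd10_chapters()
  old <- .restore_seed()
  set.seed(config$seed)
  entries <- do.call(rbind, lapply(names(alloc), function(ch) {
    .generate_chapter_entries(ch, alloc[[ch]], tab)
  }))
  if (config$title_collision && nrow(entries) >= 2) {
    # duplicate one title onto a second code of the same chapter when possible
    ch_counts <- table(entries$chapter)
    ch <- names(ch_counts)[which.max(ch_counts)]
    idx <- which(entries$chapter == ch)[1:2]
    entries$title[idx[2]] <- entries$title[idx[1]]
  }
  .reinstate_seed(old)

  entries$is_external_cause <- entries$chapter == "XX"
  entries$is_injury <- entries$chapter == "XIX"
  entries$is_ill_defined <- entries$chapter == "XVIII"
  entries$selectable_as_ucod <- !entries$is_injury & entries$chapter != "XXI"
  entries <- entries[order(entries$code), ]
  rownames(entries) <- NULL
  class(entries) <- c("codebook", "data.frame")
  validate_codebook(entries)
  entries
}

#' Validate a codebook's structural invariants
#'
#' Checks code uniqueness and pattern, chapter consistency with the built-in
#' letter-range table, and flag/chapter coherence. Called by [build_codebook()]
#' and [read_codebook()]; exported so externally supplied codebooks can be
#' vetted.
#'
#' @param cb a `codebook` data.frame.
#' @return the codebook, invisibly; stops on violation.
#' @export
validate_codebook <- function(cb) {
  stopifnot(is.data.frame(cb))
  need <- c("code", "title", "chapter", "is_external_cause", "is_injury",
            "is_ill_defined", "selectable_as_ucod")
  if (!all(need %in% names(cb))) stop("codebook missing columns")
  if (anyDuplicated(cb$code)) stop("codebook codes are not unique")
  if (!all(is_valid_code(cb$code))) stop("codebook contains malformed codes")
  if (!identical(map_code_to_chapter(cb$code), cb$chapter)) {
    stop("codebook chapter assignment inconsistent with the chapter range table")
  }
  if (any(cb$is_external_cause & cb$chapter != "XX")) stop("external-cause flag outside chapter XX")
  if (any(cb$is_injury & cb$chapter != "XIX")) stop("injury flag outside chapter XIX")
  if (any(cb$is_ill_defined & cb$chapter != "XVIII")) stop("ill-defined flag outside chapter XVIII")
  if (any(cb$is_injury & cb$selectable_as_ucod)) stop("injury codes must not be selectable as UCOD")
  invisible(cb)
}

#' @export
print.codebook <- function(x, ...) {
  cat("<codebook> ", nrow(x), " codes across ",
      length(unique(x$chapter)), " ICD-10 chapters\n", sep = "")
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("... and", nrow(x) - 5, "more codes\n")
  invisible(x)
}

#' Write / read a codebook as JSON
#'
#' Serialised as `{code: {title, chapter, is_external_cause, is_injury,
#' is_ill_defined, selectable_as_ucod}}`.
#'
#' @param cb a `codebook`.
#' @param path file path.
#' @return `write_codebook` returns `path` invisibly; `read_codebook` returns
#'   a validated `codebook`.
#' @export
write_codebook <- function(cb, path) {
  validate_codebook(cb)
  entries <- lapply(seq_len(nrow(cb)), function(i) {
    as.list(cb[i, setdiff(names(cb), "code")])
  })
  names(entries) <- cb$code
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  raw <- jsonlite::read_json(path)
  cb <- do.call(rbind, lapply(names(raw), function(code) {
    e <- raw[[code]]
    data.frame(code = code, title = e$title, chapter = e$chapter,
               is_external_cause = e$is_external_cause,
               is_injury = e$is_injury,
               is_ill_defined = e$is_ill_defined,
               selectable_as_ucod = e$selectable_as_ucod,
               stringsAsFactors = FALSE)
  }))
  class(cb) <- c("codebook", "data.frame")
  validate_codebook(cb)
  cb
}

# save/restore .Random.seed so generator calls do not clobber the caller's RNG
.restore_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.reinstate_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
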