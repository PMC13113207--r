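#' ICD-10 chapter boundary table
#'
#' The 22 chapters of ICD-10 (2016 boundaries), each defined by an inclusive
#' range of three-character category codes. Chapter membership of any code is
#' decided purely by its letter and two-digit number, so the table is a
#' versioned constant rather than a shipped database.
#'
#' @return A data.frame with columns `chapter` (roman numeral), `from`, `to`
#'   (three-character category bounds) and `title`.
#' @export
icd10_chapters <- function() {
  data.frame(
    chapter = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
                "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII", "XVIII",
                "XIX", "XX", "XXI", "XXII"),
    from = c("A00", "C00", "D50", "E00", "F00", "G00", "H00", "H60", "I00",
             "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00", "R00",
             "S00", "V01", "Z00", "U00"),
    to = c("B99", "D48", "D89", "E90", "F99", "G99", "H59", "H95", "I99",
           "J99", "K93", "L99", "M99", "N99", "O99", "P96", "Q99", "R99",
           "T98", "Y98", "Z99", "U99"),
    title = c(
      "Certain infectious and parasitic diseases",
      "Neoplasms",
      "Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism",
      "Endocrine, nutritional, and metabolic diseases",
      "Mental and behavioural disorders",
      "Diseases of the nervous system",
      "Diseases of the eye and adnexa",
      "Diseases of the ear and mastoid process",
      "Diseases of the circulatory system",
      "Diseases of the respiratory system",
      "Diseases of the digestive system",
      "Diseases of the skin and subcutaneous tissue",
      "Diseases of the musculoskeletal system and connective tissue",
      "Diseases of the genitourinary system",
      "Pregnancy, childbirth and the puerperium",
      "Certain conditions originating in the perinatal period",
      "Congenital malformations, deformations and chromosomal abnormalities",
      "Symptoms, signs and abnormal clinical and laboratory findings, not elsewhere classified",
      "Injury, poisoning and certain other consequences of external causes",
      "External causes of morbidity and mortality",
      "Factors influencing health status and contact with health services",
      "Codes for special purposes"
    ),
    stringsAsFactors = FALSE
  )
}

#' Does a string look like an ICD-10 style code?
#'
#' Codes are a letter, two digits, and an optional one-digit decimal
#' subdivision (e.g. "I21.9", "F03").
#'
#' @param code character vector.
#' @return logical vector.
#' @export
is_valid_code <- function(code) {
  grepl("^[A-Z][0-9]{2}(\\.[0-9])?$", code)
}

# numeric sort key for a three-character category: letter * 100 + number
.category_key <- function(cat3) {
  (match(substr(cat3, 1, 1), LETTERS) - 1L) * 100L +
    as.integer(substr(cat3, 2, 3))
}

#' Map ICD-10 style codes to their chapter
#'
#' Lookup in the built-in chapter boundary table; a total function on valid
#' codes.
#'
#' @param code character vector of codes such as "I21.9".
#' @return character vector of roman-numeral chapter ids.
#' @export
#' @examples
#' map_code_to_chapter(c("I21.9", "V03.1", "R99"))
map_code_to_chapter <- function(code) {
  bad <- !is_valid_code(code)
  if (any(bad)) {
    stop("malformed ICD-10 style code(s): ", paste(unique(code[bad]), collapse = ", "))
  }
  tab <- icd10_chapters()
  key <- .category_key(substr(code, 1, 3))
  lo <- .category_key(tab$from)
  hi <- .category_key(tab$to)
  idx <- vapply(key, function(k) {
    w <- which(k >= lo & k <= hi)
    if (length(w) != 1L) NA_integer_ else w
  }, integer(1))
  if (anyNA(idx)) {
    stop("code(s) outside every ICD-10 chapter range: ",
         paste(unique(code[is.na(idx)]), collapse = ", "))
  }
  tab$chapter[idx]
}
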