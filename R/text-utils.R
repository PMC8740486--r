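# Shared text primitives: tokenization with character offsets, light
# morphology (plural/lemma rules), and loaders for the shipped config tables.
# All offsets in the package are 0-based half-open.

hla_extdata <- function(file) {
  system.file("extdata", file, package = "hlatext", mustWork = TRUE)
}

#' Tokenize text, keeping character offsets
#'
#' Tokens are maximal runs of letters, digits and the in-word characters
#' `@ * : ' ( ) -` (so allele surfaces like `B(*)1301` and placeholder tags
#' like `@GENE` stay single tokens).  Offsets are 0-based half-open into
#' `text`.
#'
#' @param text a single character string.
#' @return data frame with columns `token`, `norm` (lower-cased, edge
#'   punctuation stripped), `start`, `end`.
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), norm = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[A-Za-z0-9@*:'()-]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), norm = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tok <- substring(text, start + 1L, start + len)
  norm <- tolower(gsub("^[^A-Za-z0-9@]+|[^A-Za-z0-9@]+$", "", tok, perl = TRUE))
  data.frame(token = tok, norm = norm, start = start,
             end = start + len, stringsAsFactors = FALSE)
}

# Irregular plural pairs used in both directions.
.irregular_plurals <- c(
  analysis = "analyses", diagnosis = "diagnoses", prognosis = "prognoses",
  sclerosis = "scleroses", psychosis = "psychoses", metastasis = "metastases",
  carcinoma = "carcinomas", syndrome = "syndromes", virus = "viruses",
  child = "children", man = "men", woman = "women", foot = "feet",
  tooth = "teeth", datum = "data", criterion = "criteria"
)

#' Pluralize an English keyword (rule-based)
#'
#' Simple s/es rules plus an irregular-noun table; used to widen the disease
#' dictionary with plural variants.
#' @param word a single word or multiword keyword (final word is pluralized).
#' @return the plural form, or `NA` when the rule output equals the input.
#' @export
pluralize <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  parts <- strsplit(word, " ", fixed = TRUE)[[1]]
  w <- parts[length(parts)]
  lw <- tolower(w)
  pl <- if (lw %in% names(.irregular_plurals)) {
    unname(.irregular_plurals[lw])
  } else if (grepl("[^aeiou]y$", lw)) {
    sub("y$", "ies", lw)
  } else if (grepl("(s|x|z|ch|sh)$", lw)) {
    paste0(lw, "es")
  } else if (grepl("s$", lw)) {
    lw  # already plural-looking; no variant
  } else {
    paste0(lw, "s")
  }
  if (identical(pl, lw)) return(NA_character_)
  parts[length(parts)] <- pl
  paste(parts, collapse = " ")
}

#' Singularize an English word (rule-based)
#'
#' Inverse of [pluralize()]; used as the default lemmatizer for dictionary
#' keywords and population surfaces.  Words whose singular would be ambiguous
#' (e.g. ending in `-ss`, `-us`, `-is`) are left unchanged.
#' @param word a single word.
#' @return the singular form (possibly identical to the input).
#' @export
singularize <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  lw <- tolower(word)
  irr <- names(.irregular_plurals)[match(lw, .irregular_plurals)]
  if (!is.na(irr)) return(irr)
  if (grepl("ies$", lw) && nchar(lw) > 4L) return(sub("ies$", "y", lw))
  if (grepl("(ss|us|is)$", lw)) return(lw)
  if (grepl("(ses|xes|zes|ches|shes)$", lw)) return(sub("es$", "", lw))
  if (grepl("s$", lw)) return(sub("s$", "", lw))
  lw
}

# Candidate lemmas for an inflected token, most specific first.  Dictionary
# lookups try each candidate and keep the first hit, so no full morphology
# model is needed.
lemma_candidates <- function(token) {
  t <- tolower(token)
  out <- t
  if (grepl("ied$", t)) out <- c(out, sub("ied$", "y", t))
  if (grepl("ies$", t)) out <- c(out, sub("ies$", "y", t))
  if (grepl("ed$", t)) {
    out <- c(out, sub("d$", "", t), sub("ed$", "", t),
             sub("([a-z])\\1ed$", "\\1", t))
  }
  if (grepl("ing$", t)) {
    out <- c(out, sub("ing$", "", t), sub("ing$", "e", t),
             sub("([a-z])\\1ing$", "\\1", t))
  }
  if (grepl("es$", t)) out <- c(out, sub("es$", "", t))
  if (grepl("s$", t)) out <- c(out, sub("s$", "", t))
  unique(out)
}

# First candidate lemma present in `dictionary` (a character vector), else NA.
lemma_lookup <- function(token, dictionary) {
  cand <- lemma_candidates(token)
  hit <- cand[cand %in% dictionary]
  if (length(hit)) hit[1L] else NA_character_
}

#' Load the shipped stopword list
#' @return character vector of lower-case stopwords.
#' @export
default_stopwords <- function() {
  readLines(hla_extdata("stopwords.txt"), warn = FALSE)
}
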