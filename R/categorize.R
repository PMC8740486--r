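# Study-category assignment from MeSH tree positions plus
# drug/allele/disease co-mention rules, and the anchored n-gram biomarker
# query.

.category_levels <- c("Diseases", "Transplantation", "SignsSymptoms",
                      "TherapeuticsADR")

#' Assign study categories to one abstract
#'
#' Tree-number rules: any disease mention under `C23` (pathological
#' conditions, signs and symptoms) gives `SignsSymptoms`; under `C20.452`
#' (graft-versus-host disease) or `E04` (surgical/transplantation
#' procedures) gives `Transplantation`; `TherapeuticsADR` requires a
#' sentence co-mentioning drug + allele + disease where additionally the
#' disease falls in the adverse-drug-reaction MeSH branch, or the sentence
#' contains a `reactions` / `-induced` token, or the disease keyword itself
#' contains `-induced`; any remaining disease-branch (`C`) hit gives
#' `Diseases`.  An abstract may carry several categories.  Disease mentions
#' whose descriptor has no tree number are ignored for categorization.
#'
#' @param mentions mention data frame for one abstract (columns `kind`,
#'   `canonical`, `surface`, `sentence_index`).
#' @param sentences sentence data frame for the same abstract (`index`,
#'   `text`); used for the token conditions of the ADR rule.
#' @param disease_lexicon an `hla_disease_lexicon` (supplies tree numbers).
#' @param adr_branch tree prefix of the adverse-drug-reaction branch
#'   (default `C25`, chemically-induced disorders).
#' @return character vector, a subset of
#'   `c("Diseases", "Transplantation", "SignsSymptoms", "TherapeuticsADR")`
#'   in that fixed order.
#' @export
categorize_abstract <- function(mentions, sentences, disease_lexicon,
                                adr_branch = "C25") {
  dm <- mentions[mentions$kind == "disease", , drop = FALSE]
  if (!nrow(dm)) return(character(0))
  trees <- lapply(dm$canonical, function(id)
    mesh_tree_numbers(disease_lexicon, id))
  rooted <- lengths(trees) > 0L
  if (any(!rooted)) {
    message("ignoring ", sum(!rooted),
            " disease mention(s) with no tree number")
  }
  all_trees <- unlist(trees[rooted], use.names = FALSE)
  starts_with <- function(x, prefix) {
    substr(x, 1L, nchar(prefix)) == prefix &
      (nchar(x) == nchar(prefix) |
         substr(x, nchar(prefix) + 1L, nchar(prefix) + 1L) == ".")
  }
  cats <- character(0)
  if (any(starts_with(all_trees, "C23"))) cats <- c(cats, "SignsSymptoms")
  if (any(starts_with(all_trees, "C20.452")) ||
      any(starts_with(all_trees, "E04")))
    cats <- c(cats, "Transplantation")

  # ADR: a sentence with drug + allele + disease and one of three signals
  adr <- FALSE
  sidx <- intersect(
    intersect(mentions$sentence_index[mentions$kind == "drug"],
              mentions$sentence_index[mentions$kind == "allele"]),
    mentions$sentence_index[mentions$kind == "disease"])
  for (s in sidx) {
    srow <- sentences[sentences$index == s, , drop = FALSE]
    stext <- if (nrow(srow)) tolower(srow$text[1]) else ""
    sdm <- dm[dm$sentence_index == s, , drop = FALSE]
    s_trees <- unlist(lapply(sdm$canonical, function(id)
      mesh_tree_numbers(disease_lexicon, id)), use.names = FALSE)
    in_adr_branch <- length(s_trees) &&
      any(starts_with(s_trees, adr_branch))
    toks <- tokenize_text(stext)$token
    token_signal <- any(toks == "reactions") | any(grepl("-induced$", toks))
    keyword_signal <- any(grepl("-induced", tolower(sdm$surface),
                                fixed = TRUE))
    if (in_adr_branch || token_signal || keyword_signal) {
      adr <- TRUE
      break
    }
  }
  if (adr) cats <- c(cats, "TherapeuticsADR")

  remaining <- all_trees[substr(all_trees, 1L, 1L) == "C" &
                           !starts_with(all_trees, "C23") &
                           !starts_with(all_trees, "C20.452")]
  if (length(remaining)) cats <- c(cats, "Diseases")
  .category_levels[.category_levels %in% cats]
}

#' Keywords co-occurring with an anchor token, n-gram-ranked
#'
#' Used for biomarker mining: returns the bigrams ending in the anchor
#' token (`"genetic marker"`, `"risk marker"` ...) ranked by corpus
#' frequency, ties broken lexicographically.  Stopwords are removed before
#' pairing, so `"is a marker"` contributes nothing.
#'
#' @param sentences character vector of sentence texts (or a data frame
#'   with a `text` column).
#' @param anchor anchor token (default `"marker"`).
#' @param stopwords removed before pairing; default [default_stopwords()].
#' @return data frame with columns `ngram`, `count` (empty when the anchor
#'   is absent from the corpus).
#' @export
biomarker_query <- function(sentences, anchor = "marker",
                            stopwords = default_stopwords()) {
  if (is.data.frame(sentences)) sentences <- sentences$text
  anchor <- tolower(anchor)
  pairs <- character(0)
  for (text in sentences) {
    toks <- tokenize_text(text)$norm
    toks <- toks[nzchar(toks) & !(toks %in% stopwords)]
    hit <- which(toks == anchor)
    hit <- hit[hit > 1L]
    if (length(hit)) pairs <- c(pairs, paste(toks[hit - 1L], anchor))
  }
  if (!length(pairs)) {
    return(data.frame(ngram = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(pairs)
  out <- data.frame(ngram = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$ngram), , drop = FALSE]
  row.names(out) <- NULL
  out
}
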