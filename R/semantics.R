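# Hybrid sentence-polarity scheme: n-gram label lexicon -> coding vector ->
# stage-1 label, combined with the root-verb polarity from a (pluggable)
# dependency parse, into one of six final sentence labels.

.stage1_levels <- c("positive", "negative", "negation", "complex",
                    "ambiguous", "others")
.verb_classes <- c("positive", "negative", "investigatory", "unknown")
.final_levels <- c("Positive", "Negative", "Complex", "Ambiguous",
                   "Investigatory", "Others")

#' Load the semantic label lexicon
#'
#' The shipped table (`semantic_labels_synthetic.tsv`) is a synthetic
#' stand-in for a manually curated association-label lexicon, sized to the
#' published split of 1107 positive and 20 negative labels: positive
#' entries are association verbs plus adverb-verb bigrams
#' (`"significantly associated"`), negative entries protection/resistance
#' phrases.  Negation words default to `not`, `none`, `no`.
#'
#' @param path optional TSV (`surface`, `polarity`) overriding the shipped
#'   table.
#' @param negation_path optional TSV (`surface`) overriding the shipped
#'   negation word list.
#' @return object of class `hla_label_lexicon`: list of character vectors
#'   `positive`, `negative`, `negation`.
#' @export
load_label_lexicon <- function(path = NULL, negation_path = NULL) {
  if (is.null(path)) path <- hla_extdata("semantic_labels_synthetic.tsv")
  if (is.null(negation_path)) negation_path <- hla_extdata("negation_words.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  neg <- utils::read.delim(negation_path, stringsAsFactors = FALSE)
  lex <- list(positive = tolower(tab$surface[tab$polarity == "positive"]),
              negative = tolower(tab$surface[tab$polarity == "negative"]),
              negation = tolower(neg$surface))
  if (length(intersect(lex$positive, lex$negative)))
    stop("label lexicon has surfaces in both positive and negative sets")
  if (!length(lex$positive) || !length(lex$negative) || !length(lex$negation))
    stop("label lexicon sets must be non-empty")
  structure(.index_label_lexicon(lex), class = "hla_label_lexicon")
}

# Index label surfaces by first token for fast sentence scanning.
.index_label_lexicon <- function(lex) {
  surf <- c(lex$positive, lex$negative, lex$negation)
  set <- rep(c("positive", "negative", "negation"),
             c(length(lex$positive), length(lex$negative),
               length(lex$negation)))
  words <- strsplit(surf, " ", fixed = TRUE)
  cache <- new.env(parent = emptyenv())
  cache$surf <- surf
  cache$set <- set
  cache$words <- words
  cache$first_word_index <- split(seq_along(surf),
                                  vapply(words, `[`, character(1), 1L))
  lex$cache <- cache
  lex
}

#' Load the root-verb polarity lexicon
#'
#' @param path optional TSV (`lemma`, `class`) overriding the shipped table.
#' @return named character vector: verb lemma -> class in
#'   `positive` / `negative` / `investigatory`.
#' @export
load_verb_polarity <- function(path = NULL) {
  if (is.null(path)) path <- hla_extdata("verb_polarity.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(tab$lemma),
            all(tab$class %in% c("positive", "negative", "investigatory")))
  stats::setNames(tab$class, tolower(tab$lemma))
}

#' Detect label presence and build the coding vector
#'
#' Tokenizes the sentence and searches the positive, negative and negation
#' label sets (multiword labels match as token sequences; when labels
#' overlap, the longest match wins so `"negatively associated"` does not
#' also fire the positive label `"associated"`).  Carrier-status guard: the
#' tokens `negative`/`positive` within `k_guard` tokens after an allele
#' mention describe allele carriage (`"HLA-B27 negative"` = absence of the
#' allele), never association polarity, and are ignored.
#'
#' @param text sentence text.
#' @param label_lexicon an `hla_label_lexicon`.
#' @param allele_mentions mention data frame for this sentence (only
#'   `start`/`end` of `kind == "allele"` rows are used); may be `NULL`.
#' @param k_guard token window of the carrier-status guard (default 2).
#' @return list (class `coding_vector`) with logicals `has_pos`, `has_neg`,
#'   `has_negation` and attribute `labels` (the surviving matched labels).
#' @export
detect_labels <- function(text, label_lexicon, allele_mentions = NULL,
                          k_guard = 2L) {
  stopifnot(inherits(label_lexicon, "hla_label_lexicon"))
  toks <- tokenize_text(text)
  n <- nrow(toks)
  cv <- function(p, n_, ng, labels = character(0)) {
    structure(list(has_pos = p, has_neg = n_, has_negation = ng),
              labels = labels, class = "coding_vector")
  }
  if (!n) return(cv(FALSE, FALSE, FALSE))
  norm <- toks$norm

  allele_tok <- rep(FALSE, n)
  if (!is.null(allele_mentions) && nrow(allele_mentions)) {
    am <- allele_mentions[allele_mentions$kind == "allele", , drop = FALSE]
    for (i in seq_len(nrow(am))) {
      allele_tok <- allele_tok |
        (toks$start < am$end[i] & toks$end > am$start[i])
    }
  }

  if (is.null(label_lexicon$cache))
    label_lexicon <- .index_label_lexicon(label_lexicon)
  cache <- label_lexicon$cache
  cand <- list()
  for (s in seq_len(n)) {
    hits <- cache$first_word_index[[norm[s]]]
    for (h in hits) {
      words <- cache$words[[h]]
      L <- length(words)
      if (s + L - 1L > n) next
      if (L == 1L || all(norm[seq(s, s + L - 1L)] == words)) {
        cand[[length(cand) + 1L]] <- data.frame(
          start = s, len = L, set = cache$set[h],
          surface = cache$surf[h], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand)) return(cv(FALSE, FALSE, FALSE))
  cand <- do.call(rbind, cand)
  cand$end <- cand$start + cand$len - 1L
  cand <- cand[order(-cand$len, cand$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(cand)) > i &
                 cand$start <= cand$end[i] & cand$end >= cand$start[i])
    keep[j] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]

  # carrier-status guard on surviving single-token negative/positive labels
  if (any(allele_tok)) {
    allele_idx <- which(allele_tok)
    guarded <- vapply(seq_len(nrow(cand)), function(i) {
      cand$len[i] == 1L &&
        cand$surface[i] %in% c("negative", "positive") &&
        any(cand$start[i] - allele_idx >= 1L &
              cand$start[i] - allele_idx <= k_guard)
    }, logical(1))
    cand <- cand[!guarded, , drop = FALSE]
  }
  cv(any(cand$set == "positive"), any(cand$set == "negative"),
     any(cand$set == "negation"), labels = cand$surface)
}

#' Map a coding vector to the stage-1 label
#'
#' Total mapping over the 8 presence combinations of (positive, negative,
#' negation): positive-only is `positive`, negative-only `negative`,
#' negation-only `negation`, positive+negative (with or without negation)
#' `complex`, one polarity plus negation `ambiguous`, nothing `others`.
#'
#' @param has_pos,has_neg,has_negation logicals (vectorized), or pass a
#'   `coding_vector` as `has_pos`.
#' @return character vector of stage-1 labels.
#' @export
code_to_stage1_label <- function(has_pos, has_neg = NULL,
                                 has_negation = NULL) {
  if (inherits(has_pos, "coding_vector")) {
    v <- has_pos
    has_pos <- v$has_pos
    has_neg <- v$has_neg
    has_negation <- v$has_negation
  }
  stopifnot(length(has_pos) == length(has_neg),
            length(has_pos) == length(has_negation))
  out <- character(length(has_pos))
  for (i in seq_along(has_pos)) {
    p <- has_pos[i]; ng <- has_neg[i]; nn <- has_negation[i]
    out[i] <- if (p && ng) "complex"
    else if (p && nn) "ambiguous"
    else if (ng && nn) "ambiguous"
    else if (p) "positive"
    else if (ng) "negative"
    else if (nn) "negation"
    else "others"
  }
  out
}

#' Replace entity mentions with placeholder tags
#'
#' Allele mentions become `@GENE`, disease mentions `@DISEASE`; all other
#' text is unchanged.  Masking keeps multiword entities as single tokens so
#' downstream parsing sees one node per entity.  Replacement runs
#' right-to-left so earlier offsets stay valid.
#'
#' @param text sentence text.
#' @param mentions mention data frame with `kind`, `start`, `end` for this
#'   sentence (kinds other than allele/disease are ignored).
#' @return masked sentence text.
#' @export
mask_entities <- function(text, mentions) {
  m <- mentions[mentions$kind %in% c("allele", "disease"), , drop = FALSE]
  if (!nrow(m)) return(text)
  m <- m[order(m$start), , drop = FALSE]
  if (nrow(m) > 1L && any(m$start[-1] < m$end[-nrow(m)]))
    stop("overlapping mention spans; resolve matches upstream")
  for (i in rev(seq_len(nrow(m)))) {
    tag <- if (m$kind[i] == "allele") "@GENE" else "@DISEASE"
    text <- paste0(substr(text, 1L, m$start[i]), tag,
                   substring(text, m$end[i] + 1L))
  }
  text
}

# Auxiliaries and modals skipped when hunting for the root verb.
.aux_verbs <- c("is", "are", "was", "were", "be", "been", "being", "am",
                "has", "have", "had", "having", "do", "does", "did",
                "can", "could", "may", "might", "must", "shall", "should",
                "will", "would")

# Verbs recognizable by the fallback root finder beyond the polarity
# lexicon (class "unknown" unless the polarity lexicon says otherwise).
.common_verbs <- c("be", "have", "do", "report", "observe", "find",
                   "detect", "identify", "show", "suggest", "indicate",
                   "confirm", "reveal", "demonstrate", "compare", "include",
                   "perform", "test", "carry", "express", "genotype",
                   "type", "treat", "diagnose", "enroll", "recruit",
                   "measure", "collect", "present", "note", "describe",
                   "document", "remain", "occur", "develop", "undergo",
                   "consider", "select", "obtain", "analyze", "analyse")

#' Extract the root verb of a masked sentence and classify its polarity
#'
#' With an injected dependency parser the verb heading the parse tree is
#' used.  The default fallback is a part-of-speech heuristic: the first
#' verb-like token outside a to-infinitival purpose clause, skipping
#' auxiliaries, is treated as the root; a sentence opening with a purpose
#' clause (`"To investigate ..."`) takes that infinitive as root.  The
#' lemma is classified via the verb-polarity lexicon; lemmas absent from it
#' are `"unknown"`.
#'
#' @param masked_text sentence text (typically after [mask_entities()]).
#' @param verb_polarity named vector from [load_verb_polarity()].
#' @param parser optional function(text) returning the root verb token (or
#'   a list with element `verb`).
#' @return list with `verb` (lemma, `""` if none found) and `class`
#'   (`positive` / `negative` / `investigatory` / `unknown`).
#' @export
root_verb <- function(masked_text, verb_polarity = load_verb_polarity(),
                      parser = NULL) {
  classify <- function(lemma) {
    if (is.na(lemma) || !nzchar(lemma))
      return(list(verb = "", class = "unknown"))
    cls <- if (lemma %in% names(verb_polarity))
      unname(verb_polarity[lemma]) else "unknown"
    list(verb = lemma, class = cls)
  }
  if (!is.null(parser)) {
    res <- tryCatch(parser(masked_text), error = function(e) NULL)
    if (is.null(res)) return(list(verb = "", class = "unknown"))
    v <- if (is.list(res)) res$verb else res
    lemma <- lemma_lookup(v, names(verb_polarity))
    if (is.na(lemma)) lemma <- lemma_candidates(v)[length(lemma_candidates(v))]
    return(classify(lemma))
  }
  toks <- tokenize_text(masked_text)$norm
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(list(verb = "", class = "unknown"))
  dict <- unique(c(names(verb_polarity), .common_verbs))
  # purpose-clause opener: "To VERB ..." is the root (investigatory style)
  if (length(toks) >= 2L && toks[1] == "to") {
    lemma <- lemma_lookup(toks[2], dict)
    if (!is.na(lemma)) return(classify(lemma))
  }
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (t %in% .aux_verbs) next
    if (i > 1L && toks[i - 1L] == "to") next  # mid-sentence infinitive
    lemma <- lemma_lookup(t, dict)
    if (!is.na(lemma) && !(lemma %in% c("be", "have", "do")))
      return(classify(lemma))
  }
  list(verb = "", class = "unknown")
}

#' Combine stage-1 label and root-verb class into the final sentence label
#'
#' Decision table: agreement between a positive stage-1 label and a
#' positive root verb gives `Positive` (likewise `Negative`); stage-1
#' `complex` is `Complex`; stage-1 `ambiguous` or `negation` is
#' `Ambiguous`; an investigatory root verb with stage-1 in
#' others/positive/negative (without polarity agreement) gives
#' `Investigatory`; everything else — including polarity disagreement — is
#' `Others`.
#'
#' @param stage1 stage-1 label (see [code_to_stage1_label()]).
#' @param verb_class root-verb class (see [root_verb()]).
#' @return one of `Positive`, `Negative`, `Complex`, `Ambiguous`,
#'   `Investigatory`, `Others` (vectorized).
#' @export
annotate_sentence <- function(stage1, verb_class) {
  stopifnot(all(stage1 %in% .stage1_levels),
            all(verb_class %in% .verb_classes))
  n <- max(length(stage1), length(verb_class))
  stage1 <- rep_len(stage1, n)
  verb_class <- rep_len(verb_class, n)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- stage1[i]; v <- verb_class[i]
    out[i] <- if (s == "complex") "Complex"
    else if (s %in% c("ambiguous", "negation")) "Ambiguous"
    else if (s == "positive" && v == "positive") "Positive"
    else if (s == "negative" && v == "negative") "Negative"
    else if (v == "investigatory") "Investigatory"
    else "Others"
  }
  out
}

# POS guesses used by the n-gram harvester (lexicon + suffix heuristics).
.is_adverb <- function(tok) {
  grepl("ly$", tok) | tok %in% c("very", "well", "often", "together")
}
.is_verbish <- function(tok, dict) {
  vapply(tok, function(t) {
    !is.na(lemma_lookup(t, dict)) || grepl("(ed|ing)$", t)
  }, logical(1))
}

#' Harvest frequency-ranked n-gram label candidates from a corpus
#'
#' Tokenizes the retained sentences, removes stopwords, applies the
#' (pluggable) lemmatizer, and counts n-grams restricted to
#' part-of-speech patterns: single verbs/adverbs for n = 1, and adjacent
#' adverb-verb combinations (at least one adverb and one verb) for
#' n = 2, 3.  Candidates at or above the frequency cutoff are returned with
#' counts, descending, ties broken lexicographically — a ranked list meant
#' for manual curation into the label lexicon.
#'
#' @param sentences character vector of sentence texts (or a sentence data
#'   frame with a `text` column).
#' @param n_values subset of 1:3.
#' @param freq_cutoff minimum corpus frequency (default 10).
#' @param stopwords character vector; default [default_stopwords()].
#' @param lemmatize function applied to each token; the default keeps the
#'   surface form so harvested candidates read as they appear in text.
#' @return data frame with columns `ngram`, `n`, `count`.
#' @export
build_ngram_candidates <- function(sentences, n_values = c(1L, 2L, 3L),
                                   freq_cutoff = 10L,
                                   stopwords = default_stopwords(),
                                   lemmatize = identity) {
  stopifnot(length(n_values) >= 1L, all(n_values %in% 1:3),
            freq_cutoff >= 1L)
  if (is.data.frame(sentences)) sentences <- sentences$text
  dict <- unique(c(names(load_verb_polarity()), .common_verbs))
  grams <- list()
  for (text in sentences) {
    toks <- tokenize_text(text)$norm
    toks <- toks[nzchar(toks) & !(toks %in% stopwords) &
                   grepl("[a-z]", toks)]
    toks <- vapply(toks, lemmatize, character(1), USE.NAMES = FALSE)
    if (!length(toks)) next
    adv <- .is_adverb(toks)
    vb <- .is_verbish(toks, dict)
    for (n in sort(n_values)) {
      if (length(toks) < n) next
      for (s in seq_len(length(toks) - n + 1L)) {
        idx <- seq(s, s + n - 1L)
        ok <- if (n == 1L) adv[s] || vb[s] else
          all(adv[idx] | vb[idx]) && any(adv[idx]) && any(vb[idx])
        if (ok) {
          grams[[length(grams) + 1L]] <-
            c(paste(toks[idx], collapse = " "), n)
        }
      }
    }
  }
  if (!length(grams)) {
    return(data.frame(ngram = character(), n = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  g <- do.call(rbind, grams)
  tab <- table(paste(g[, 2], g[, 1], sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(ngram = vapply(parts, `[`, character(1), 2L),
                    n = as.integer(vapply(parts, `[`, character(1), 1L)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[out$count >= freq_cutoff, , drop = FALSE]
  out <- out[order(-out$count, out$ngram), , drop = FALSE]
  row.names(out) <- NULL
  out
}
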