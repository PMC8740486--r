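# Dictionary matching over the two lower-cased search variants of a
# sentence, with keyword-class-specific boundary rules and
# longest-match-wins resolution of overlapping hits.

# Boundary character classes.  A surface matches only when the characters
# flanking it (if any) fall outside the class.  Alleles extend the class
# with '*' and ':' because standard \b word boundaries fail next to '*'.
.boundary_class <- list(
  allele = "[A-Za-z0-9*:]",
  word = "[A-Za-z0-9]"
)

.empty_mentions <- function() {
  data.frame(kind = character(), surface = character(),
             canonical = character(), start = integer(), end = integer(),
             variant = character(), ambiguous = logical(),
             stringsAsFactors = FALSE)
}

# Find all boundary-respecting occurrences of `surface` in `text`
# (both already lower-cased).  Returns 0-based half-open starts/ends.
.find_surface <- function(text, surface, boundary) {
  hits <- gregexpr(surface, text, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  len <- nchar(surface)
  n <- nchar(text)
  keep <- vapply(hits, function(p) {
    before_ok <- p == 1L || !grepl(boundary, substr(text, p - 1L, p - 1L))
    after_ok <- p + len > n || !grepl(boundary, substr(text, p + len, p + len))
    before_ok && after_ok
  }, logical(1))
  if (!any(keep)) return(NULL)
  p <- as.integer(hits[keep])
  data.frame(start = p - 1L, end = p + len - 1L)
}

# Greedy longest-match-wins, left-most tie-breaking, over one sentence's
# candidate mentions (already deduplicated by span).
.resolve_overlaps <- function(m) {
  m <- m[order(-(m$end - m$start), m$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(m)) > i &
                 m$start < m$end[i] & m$end > m$start[i])
    keep[j] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  m[order(m$start, m$end), , drop = FALSE]
}

# Match a compiled surface table (columns surface_a, surface_b, canonical,
# ambiguous) against a vector of sentence texts.  Returns one mention data
# frame with a `.row` column giving the 1-based index into `texts`.
.match_corpus <- function(texts, table, boundary, kind,
                          resolve = TRUE) {
  empty <- cbind(.row = integer(), .empty_mentions())
  if (!nrow(table) || !length(texts)) return(empty)
  pre <- lapply(texts, function(t) {
    if (is.na(t)) t <- ""
    preprocess_variants(t)
  })
  ta <- vapply(pre, `[[`, character(1), "a")
  tb <- vapply(pre, `[[`, character(1), "b")
  found <- list()
  for (i in seq_len(nrow(table))) {
    sa <- table$surface_a[i]
    sb <- table$surface_b[i]
    cand_a <- if (nzchar(sa)) grepl(sa, ta, fixed = TRUE) else
      logical(length(ta))
    # variant B is scanned even when the surface has no special characters:
    # the sentence may carry the specials ("Graves' disease" vs keyword
    # "graves disease")
    cand_b <- if (nzchar(sb)) grepl(sb, tb, fixed = TRUE) else
      logical(length(tb))
    for (s in which(cand_a | cand_b)) {
      if (cand_a[s]) {
        h <- .find_surface(ta[s], sa, boundary)
        if (!is.null(h)) {
          found[[length(found) + 1L]] <- data.frame(
            .row = s, start = h$start, end = h$end, i = i, variant = "A",
            stringsAsFactors = FALSE)
        }
      }
      if (cand_b[s]) {
        h <- .find_surface(tb[s], sb, boundary)
        if (!is.null(h)) {
          map <- pre[[s]]$map_b
          found[[length(found) + 1L]] <- data.frame(
            .row = s, start = map[h$start + 1L], end = map[h$end] + 1L,
            i = i, variant = "B", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(found)) return(empty)
  raw <- do.call(rbind, found)
  # variant A preferred when both variants yield the same span
  raw <- raw[order(raw$.row, raw$start, raw$end, raw$variant), , drop = FALSE]
  raw <- raw[!duplicated(raw[, c(".row", "start", "end", "i")]), ,
             drop = FALSE]
  out <- do.call(rbind, lapply(split(raw, raw$.row), function(m) {
    m <- m[!duplicated(m[, c("start", "end")]), , drop = FALSE]
    if (resolve) m <- .resolve_overlaps(m)
    m
  }))
  data.frame(.row = out$.row, kind = kind,
             surface = substring(texts[out$.row], out$start + 1L, out$end),
             canonical = table$canonical[out$i],
             start = out$start, end = out$end, variant = out$variant,
             ambiguous = table$ambiguous[out$i],
             stringsAsFactors = FALSE)
}

.match_one <- function(text, table, boundary, kind) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- .match_corpus(text, table, boundary, kind)
  m$.row <- NULL
  row.names(m) <- NULL
  m
}

# Compiled surface tables are cached inside each lexicon's `cache`
# environment so repeated matching does not recompile.
.cached <- function(lexicon, key, build) {
  cache <- lexicon$cache
  if (is.null(cache)) return(build())
  if (is.null(cache[[key]])) cache[[key]] <- build()
  cache[[key]]
}

.compile_disease_table <- function(lexicon) {
  .cached(lexicon, "table", function() {
    e <- lexicon$entries
    # one row per surface; smallest mesh_id wins for ambiguous keywords
    e <- e[order(e$surface, e$mesh_id), , drop = FALSE]
    e <- e[!duplicated(e$surface), , drop = FALSE]
    data.frame(surface_a = e$surface,
               surface_b = vapply(e$surface,
                                  function(s) preprocess_variants(s)$b,
                                  character(1), USE.NAMES = FALSE),
               canonical = e$mesh_id, ambiguous = FALSE,
               stringsAsFactors = FALSE)
  })
}

.compile_allele_table <- function(lexicon) {
  .cached(lexicon, "table", function() {
    surf <- allele_surfaces(lexicon)
    canon <- lapply(surf, function(s) sort(lexicon$surfaces[[s]]))
    data.frame(surface_a = surf,
               surface_b = vapply(surf, function(s) preprocess_variants(s)$b,
                                  character(1), USE.NAMES = FALSE),
               canonical = vapply(canon, paste, character(1),
                                  collapse = "|"),
               ambiguous = lengths(canon) > 1L,
               stringsAsFactors = FALSE)
  })
}

.compile_drug_table <- function(lexicon) {
  data.frame(surface_a = lexicon$name,
             surface_b = vapply(lexicon$name,
                                function(s) preprocess_variants(s)$b,
                                character(1), USE.NAMES = FALSE),
             canonical = lexicon$name, ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

#' Match disease keywords in a sentence
#'
#' Both search variants are consulted: variant A (lower-cased, special
#' characters kept) and variant B (special characters removed), so
#' `Stevens-Johnson syndrome` and `Stevens Johnson syndrome` both match the
#' same keyword.  Overlapping hits resolve longest-match-wins with
#' left-most tie-breaking; mentions are deduplicated by span.
#'
#' @param text sentence text (original casing).
#' @param lexicon an `hla_disease_lexicon`.
#' @return mention data frame: `kind`, `surface` (original text),
#'   `canonical` (MeSH descriptor ID), `start`, `end` (0-based half-open),
#'   `variant` (`A`/`B`), `ambiguous`.
#' @export
match_diseases <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "hla_disease_lexicon"))
  .match_one(text, .compile_disease_table(lexicon),
             .boundary_class$word, "disease")
}

#' Match HLA allele surfaces in a sentence
#'
#' Word-boundary-based matching where the boundary class is extended with
#' `*` and `:` (so `B*1301` matches inside `...of B*1301 were...` but not
#' inside `4B1301X`).  Canonical names follow [normalize_allele()]
#' semantics; ambiguous (broad-antigen/haplotype) surfaces carry all
#' candidates joined by `|` and `ambiguous = TRUE`.
#'
#' @inheritParams match_diseases
#' @param lexicon an `hla_allele_lexicon`.
#' @return mention data frame (see [match_diseases()]).
#' @export
match_alleles <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "hla_allele_lexicon"))
  .match_one(text, .compile_allele_table(lexicon),
             .boundary_class$allele, "allele")
}

#' Keep/drop screening decision for one abstract
#'
#' An abstract is kept iff its title or abstract text contains at least one
#' HLA allele surface and at least one disease keyword (jointly across both
#' locations).
#'
#' @param record one-row data frame (or list) with `title` and `abstract`.
#' @param allele_lexicon,disease_lexicon compiled lexicons.
#' @return logical.
#' @export
screen_abstract <- function(record, allele_lexicon, disease_lexicon) {
  txt <- paste(record$title, record$abstract, sep = " \n ")
  nrow(match_alleles(txt, allele_lexicon)) > 0L &&
    nrow(match_diseases(txt, disease_lexicon)) > 0L
}

#' Retain sentences co-mentioning an allele and a disease
#'
#' @param sentences sentence data frame (`pmid`, `index`, ...).
#' @param mentions mention data frame with `pmid`, `sentence_index`, `kind`.
#' @return the subset of `sentences` with at least one allele mention and
#'   at least one disease mention in that sentence.
#' @export
filter_cooccurrence_sentences <- function(sentences, mentions) {
  if (!nrow(sentences)) return(sentences)
  key <- paste(sentences$pmid, sentences$index)
  mkey <- paste(mentions$pmid, mentions$sentence_index)
  has_allele <- key %in% mkey[mentions$kind == "allele"]
  has_disease <- key %in% mkey[mentions$kind == "disease"]
  out <- sentences[has_allele & has_disease, , drop = FALSE]
  row.names(out) <- NULL
  out
}
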