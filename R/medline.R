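# MEDLINE/PubMed XML parsing, structured-abstract cleanup, sentence
# splitting and the two lower-cased search variants used by the matchers.

# The 14 structured-abstract section labels that are stripped when they
# appear as labels followed by a colon (an optional plural "s" is accepted).
.subheading_labels <- c(
  "background", "introduction", "study objectives?", "objectives?",
  "experimental designs?", "methods?", "results?", "discussions?",
  "importance", "settings?", "designs?", "patients", "participants",
  "conclusions?"
)

#' Remove structured-abstract subheading labels
#'
#' Structured abstracts carry section labels such as `BACKGROUND:` or
#' `RESULTS:`.  The labels (background, introduction, objective, method,
#' experimental design, result, discussion, importance, setting, design,
#' study objective, patients, participants, conclusion) are removed when they
#' occur case-insensitively at the start of the text, after a newline, or
#' after sentence-final punctuation, and are followed by a colon.  All other
#' text — including the common nouns "results" or "design" mid-sentence — is
#' preserved verbatim.
#'
#' @param text character vector of abstract texts.
#' @return character vector with labels removed.
#' @export
#' @examples
#' strip_subheadings("BACKGROUND: HLA-B27 is a risk factor.")
strip_subheadings <- function(text) {
  pat <- paste0("(^|\\n[ \\t]*|(?<=[.!?;])[ \\t]+)(?:",
                paste(.subheading_labels, collapse = "|"),
                ")[ \\t]*:[ \\t]*")
  gsub(pat, "\\1", text, perl = TRUE, ignore.case = TRUE)
}

.date_from_pubdate <- function(node) {
  if (length(node) == 0L) return(NA_character_)
  y <- xml2::xml_text(xml2::xml_find_first(node, "./Year"))
  if (is.na(y)) {
    md <- xml2::xml_text(xml2::xml_find_first(node, "./MedlineDate"))
    if (is.na(md)) return(NA_character_)
    y <- regmatches(md, regexpr("[0-9]{4}", md))
    if (!length(y)) return(NA_character_)
  }
  months <- c(Jan = "01", Feb = "02", Mar = "03", Apr = "04", May = "05",
              Jun = "06", Jul = "07", Aug = "08", Sep = "09", Oct = "10",
              Nov = "11", Dec = "12")
  m <- xml2::xml_text(xml2::xml_find_first(node, "./Month"))
  m <- if (is.na(m)) "01" else if (m %in% names(months)) months[[m]] else
    sprintf("%02d", suppressWarnings(as.integer(m)))
  if (is.na(m)) m <- "01"
  d <- xml2::xml_text(xml2::xml_find_first(node, "./Day"))
  d <- if (is.na(d)) "01" else sprintf("%02d", suppressWarnings(as.integer(d)))
  if (is.na(d)) d <- "01"
  paste(y, m, d, sep = "-")
}

#' Parse MEDLINE/PubMed XML into abstract records
#'
#' Reads PubMed baseline/updatefiles XML (`PubmedArticle` elements) and
#' returns one row per citation that carries all required fields: PMID,
#' title, abstract text, publication date, journal and at least one
#' publication type (authors are optional unless `require_authors = TRUE`).
#' Incomplete records are skipped and logged.  Abstract section texts are
#' concatenated (structured-section labels re-inserted as `LABEL: text`) and
#' then cleaned with [strip_subheadings()].
#'
#' @param xml_source path to an XML file, or a string of XML.
#' @param require_authors logical; if `TRUE`, records without an author list
#'   are skipped too.
#' @return A data frame of class `hla_abstracts` with columns `pmid`,
#'   `title`, `abstract` (cleaned), `pub_date`, `journal`, `article_types`
#'   (list column), `authors` (list column).  The skip log is attached as
#'   attribute `"skipped"` (data frame `pmid`, `missing`).
#' @export
parse_medline <- function(xml_source, require_authors = FALSE) {
  doc <- tryCatch(
    xml2::read_xml(xml_source),
    error = function(e) stop("malformed MEDLINE XML: ", conditionMessage(e),
                             call. = FALSE)
  )
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  recs <- vector("list", length(arts))
  skipped <- list()
  for (i in seq_along(arts)) {
    a <- arts[[i]]
    cit <- xml2::xml_find_first(a, "./MedlineCitation")
    pmid <- xml2::xml_text(xml2::xml_find_first(cit, "./PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(cit, ".//ArticleTitle"))
    abs_nodes <- xml2::xml_find_all(cit, ".//Abstract/AbstractText")
    abs_parts <- vapply(abs_nodes, function(n) {
      lab <- xml2::xml_attr(n, "Label")
      txt <- xml2::xml_text(n)
      if (!is.na(lab) && nzchar(lab)) paste0(lab, ": ", txt) else txt
    }, character(1))
    abstract <- paste(abs_parts[nzchar(abs_parts)], collapse = " ")
    abstract <- strip_subheadings(abstract)
    abstract <- gsub("^\\s+|\\s+$", "", abstract)
    pub_date <- .date_from_pubdate(
      xml2::xml_find_first(cit, ".//Journal/JournalIssue/PubDate"))
    journal <- xml2::xml_text(xml2::xml_find_first(cit, ".//Journal/Title"))
    types <- xml2::xml_text(
      xml2::xml_find_all(cit, ".//PublicationTypeList/PublicationType"))
    authors <- vapply(
      xml2::xml_find_all(cit, ".//AuthorList/Author"),
      function(n) {
        ln <- xml2::xml_text(xml2::xml_find_first(n, "./LastName"))
        fn <- xml2::xml_text(xml2::xml_find_first(n, "./ForeName"))
        cn <- xml2::xml_text(xml2::xml_find_first(n, "./CollectiveName"))
        if (!is.na(ln)) paste(c(fn[!is.na(fn)], ln), collapse = " ") else
          if (!is.na(cn)) cn else NA_character_
      }, character(1))
    authors <- authors[!is.na(authors)]

    missing <- character()
    if (is.na(pmid) || !nzchar(pmid)) missing <- c(missing, "pmid")
    if (is.na(title) || !nzchar(title)) missing <- c(missing, "title")
    if (!nzchar(abstract)) missing <- c(missing, "abstract")
    if (is.na(pub_date)) missing <- c(missing, "pub_date")
    if (is.na(journal) || !nzchar(journal)) missing <- c(missing, "journal")
    if (length(types) == 0L) missing <- c(missing, "article_type")
    if (require_authors && length(authors) == 0L)
      missing <- c(missing, "authors")
    if (length(missing)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        pmid = if (is.na(pmid)) "" else pmid,
        missing = paste(missing, collapse = ","), stringsAsFactors = FALSE)
      next
    }
    recs[[i]] <- list(pmid = pmid, title = title, abstract = abstract,
                      pub_date = pub_date, journal = journal,
                      article_types = types, authors = authors)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- data.frame(
    pmid = vapply(recs, `[[`, character(1), "pmid"),
    title = vapply(recs, `[[`, character(1), "title"),
    abstract = vapply(recs, `[[`, character(1), "abstract"),
    pub_date = vapply(recs, `[[`, character(1), "pub_date"),
    journal = vapply(recs, `[[`, character(1), "journal"),
    stringsAsFactors = FALSE)
  out$article_types <- lapply(recs, `[[`, "article_types")
  out$authors <- lapply(recs, `[[`, "authors")
  if (anyDuplicated(out$pmid))
    warning("duplicate PMIDs in corpus: ",
            paste(unique(out$pmid[duplicated(out$pmid)]), collapse = ", "))
  skip_df <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(pmid = character(), missing = character(),
               stringsAsFactors = FALSE)
  attr(out, "skipped") <- skip_df
  class(out) <- c("hla_abstracts", "data.frame")
  out
}

#' @export
print.hla_abstracts <- function(x, ...) {
  cat("<hla_abstracts> ", nrow(x), " records (",
      nrow(attr(x, "skipped")), " skipped during parsing)\n", sep = "")
  print.data.frame(utils::head(x[, c("pmid", "title", "pub_date")], 5), ...)
  invisible(x)
}

# Abbreviations that never end a sentence when followed by a period.
.abbreviations <- c("al", "et", "spp", "sp", "cf", "vs", "fig", "figs",
                    "dr", "prof", "approx", "ca", "resp", "ref", "refs")

#' Split an abstract into offset-tracked sentences
#'
#' Rule-based splitter: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an upper-case letter or digit, unless the preceding token
#' is a known abbreviation (`et al.`, `spp.`, `Fig.` ...) or a single
#' initial.  Offsets are 0-based half-open into `text`, so
#' `substr(text, start + 1, end)` reproduces each sentence exactly.
#'
#' @param text a single cleaned abstract string.
#' @param pmid optional record identifier carried into the output.
#' @return data frame with columns `pmid`, `index` (0-based), `text`,
#'   `start`, `end`.
#' @export
sentence_split <- function(text, pmid = NA_character_) {
  empty <- data.frame(pmid = character(), index = integer(),
                      text = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  boundaries <- integer()  # index (1-based) of sentence-final punctuation
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      # look ahead: whitespace then capital/digit (or end of text)
      j <- i + 1L
      while (j <= n && chars[j] %in% c(" ", "\t", "\n", "\r")) j <- j + 1L
      opens_next <- j > i + 1L && j <= n && grepl("[A-Z0-9]", chars[j])
      at_end <- j > n
      if (opens_next || at_end) {
        prev <- sub(".*?([A-Za-z]+)$", "\\1",
                    substr(text, max(1L, i - 20L), i - 1L))
        is_abbrev <- chars[i] == "." &&
          (tolower(prev) %in% .abbreviations || nchar(prev) == 1L)
        if (!is_abbrev) boundaries <- c(boundaries, i)
      }
    }
    i <- i + 1L
  }
  ends <- unique(c(boundaries, n))
  out <- list()
  cursor <- 1L
  idx <- 0L
  for (e in ends) {
    s <- cursor
    while (s <= e && grepl("[ \t\n\r]", chars[s])) s <- s + 1L
    e2 <- e
    while (e2 >= s && grepl("[ \t\n\r]", chars[e2])) e2 <- e2 - 1L
    if (e2 >= s) {
      out[[length(out) + 1L]] <- data.frame(
        pmid = pmid, index = idx, text = substr(text, s, e2),
        start = s - 1L, end = e2, stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
    cursor <- e + 1L
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Sentence-split every record of a parsed corpus
#'
#' @param records an `hla_abstracts` data frame from [parse_medline()].
#' @return one data frame of sentences (see [sentence_split()]) for all
#'   records, in record order.
#' @export
corpus_sentences <- function(records) {
  parts <- lapply(seq_len(nrow(records)), function(i) {
    sentence_split(records$abstract[i], pmid = records$pmid[i])
  })
  if (!length(parts)) return(sentence_split(""))
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out
}

# Characters deleted (or, for dashes, turned into spaces) in search variant B.
.special_delete <- c("'", "’", "‘", "(", ")", "*", ":")
.special_space <- c("-", "–", "—")

#' Build the two lower-cased search variants of a sentence
#'
#' Variant A is the sentence lower-cased with special characters kept, so
#' keywords like `Graves' disease` match as written.  Variant B additionally
#' removes the special characters `- ' ( ) * :` (dashes become spaces,
#' the rest are deleted, whitespace runs collapse), so `Stevens-Johnson
#' syndrome` also matches `Stevens Johnson syndrome`.  A position map from
#' every variant-B character back to its 0-based offset in the original text
#' lets matches be reported against the original sentence.
#'
#' @param text a single sentence string.
#' @return list with elements `a` (variant A string), `b` (variant B
#'   string), and `map_b` (integer vector, 0-based original offset of each
#'   variant-B character).
#' @export
preprocess_variants <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  a <- tolower(text)
  chars <- strsplit(a, "")[[1]]
  b_chars <- character(0)
  map <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% .special_delete) next
    if (ch %in% .special_space || grepl("[ \t\n\r]", ch)) {
      if (!length(b_chars) || b_chars[length(b_chars)] == " ") next
      b_chars <- c(b_chars, " ")
      map <- c(map, i - 1L)
      next
    }
    b_chars <- c(b_chars, ch)
    map <- c(map, i - 1L)
  }
  # drop a trailing space
  if (length(b_chars) && b_chars[length(b_chars)] == " ") {
    b_chars <- b_chars[-length(b_chars)]
    map <- map[-length(map)]
  }
  list(a = a, b = paste(b_chars, collapse = ""), map_b = map)
}
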