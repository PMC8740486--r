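# Taggers for SNP rsIDs, drug mentions (with containment-based
# false-positive suppression) and population/ethnicity mentions via an
# injected token-classification backend.

#' Tag SNP rsIDs in text
#'
#' Scans for case-insensitive `rs` followed by at least two digits (no
#' upper bound), normalizes to a lower-case `rs` prefix, and returns unique
#' IDs in order of first occurrence.
#'
#' @param text a single character string.
#' @return character vector of rsIDs (possibly empty).
#' @export
#' @examples
#' tag_snps("RS12, rs345 and rs12 were tested; rs9 is too short.")
tag_snps <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  m <- gregexpr("[rR][sS][0-9]{2,}", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  ids <- substring(text, m, m + attr(m, "match.length") - 1L)
  unique(paste0("rs", substring(ids, 3L)))
}

#' Tag drug mentions in a sentence
#'
#' Dictionary matching with the same word-boundary rule as disease keywords.
#' Any drug mention whose span is fully contained in a disease-mention span
#' is discarded — e.g. `insulin` inside the disease name
#' `insulin dependent diabetes mellitus` is not a drug mention.
#'
#' @param text sentence text.
#' @param drug_lexicon an `hla_drug_lexicon` from [build_drug_lexicon()].
#' @param disease_mentions mention data frame for the same sentence (the
#'   `start`/`end` spans are used for suppression); may be empty.
#' @return mention data frame (see [match_diseases()]), `kind = "drug"`.
#' @export
tag_drugs <- function(text, drug_lexicon, disease_mentions = NULL) {
  m <- .match_one(text, .compile_drug_table(drug_lexicon),
                  .boundary_class$word, "drug")
  if (nrow(m) && !is.null(disease_mentions) && nrow(disease_mentions)) {
    dm <- disease_mentions[disease_mentions$kind == "disease", , drop = FALSE]
    contained <- vapply(seq_len(nrow(m)), function(i) {
      any(m$start[i] >= dm$start & m$end[i] <= dm$end)
    }, logical(1))
    m <- m[!contained, , drop = FALSE]
    row.names(m) <- NULL
  }
  m
}

#' Load the curated population binning tables
#'
#' Miniature stand-in tables (demonym -> country, surface -> ethnic group)
#' seeded from printed examples; both are plain TSV and editable.
#'
#' @param countries,ethnic_groups optional paths overriding the shipped
#'   tables.
#' @return list with data frames `countries` and `ethnic_groups`.
#' @export
load_population_tables <- function(countries = NULL, ethnic_groups = NULL) {
  if (is.null(countries)) countries <- hla_extdata("countries.tsv")
  if (is.null(ethnic_groups)) ethnic_groups <- hla_extdata("ethnic_groups.tsv")
  list(countries = utils::read.delim(countries, stringsAsFactors = FALSE),
       ethnic_groups = utils::read.delim(ethnic_groups,
                                         stringsAsFactors = FALSE))
}

#' Gazetteer token-classification backend
#'
#' Returns a backend function usable with [tag_populations()]: it scans a
#' text for the curated demonym/ethnic-group surfaces (labelled `NORP`) and
#' for country proper names plus a few organism genera notoriously
#' mis-labelled by model backends (labelled `GPE`).  This keeps the default
#' pipeline free of model downloads; a model-based backend can be injected
#' instead.
#'
#' @param tables population tables from [load_population_tables()].
#' @return function(text) -> data frame with columns `surface`, `label`.
#' @export
population_gazetteer_backend <- function(tables = load_population_tables()) {
  norp <- unique(c(tables$countries$surface, tables$ethnic_groups$surface))
  norp <- unique(c(norp, paste0(norp, "s")))
  gpe <- unique(c(tolower(tables$countries$country),
                  "chlamydia", "chlamydomonas"))
  tab <- data.frame(
    surface_a = c(norp, gpe),
    surface_b = vapply(c(norp, gpe),
                       function(s) preprocess_variants(s)$b, character(1),
                       USE.NAMES = FALSE),
    canonical = c(rep("NORP", length(norp)), rep("GPE", length(gpe))),
    ambiguous = FALSE, stringsAsFactors = FALSE)
  function(text) {
    m <- .match_one(text, tab, .boundary_class$word, "population")
    data.frame(surface = m$surface, label = m$canonical,
               stringsAsFactors = FALSE)
  }
}

#' Tag population/ethnicity mentions in an abstract
#'
#' Population names need not co-occur with allele/disease keywords, so the
#' whole abstract (title + text) is searched.  Of the backend's entity
#' labels only `NORP` (nationalities or religious/political groups) is
#' kept — `GPE` (geo-political entities) is discarded because it captures
#' organism scientific names in biomedical text.  Surfaces are case-folded,
#' singularized and deduplicated, then binned into countries and ethnic
#' groups via the curated tables; unmapped surfaces are flagged
#' `unbinned`.
#'
#' @param record one-row data frame (or list) with `title` and `abstract`.
#' @param backend function(text) -> data frame (`surface`, `label`);
#'   default [population_gazetteer_backend()].
#' @param tables population tables from [load_population_tables()].
#' @return data frame with columns `surface` (singularized, lower case),
#'   `bin` (`country` / `ethnic_group` / `unbinned`), `normalized`.
#' @export
tag_populations <- function(record, backend = NULL,
                            tables = load_population_tables()) {
  empty <- data.frame(surface = character(), bin = character(),
                      normalized = character(), stringsAsFactors = FALSE)
  if (is.null(backend)) backend <- population_gazetteer_backend(tables)
  txt <- paste(record$title, record$abstract, sep = " \n ")
  tags <- tryCatch(backend(txt), error = function(e) {
    warning("population NER backend unavailable: ", conditionMessage(e),
            "; proceeding without population tags")
    NULL
  })
  if (is.null(tags) || !nrow(tags)) return(empty)
  tags <- tags[tags$label == "NORP", , drop = FALSE]
  if (!nrow(tags)) return(empty)
  surf <- unique(vapply(tolower(tags$surface), singularize, character(1),
                        USE.NAMES = FALSE))
  ci <- match(surf, tables$countries$surface)
  ei <- match(surf, tables$ethnic_groups$surface)
  bin <- ifelse(!is.na(ci), "country",
                ifelse(!is.na(ei), "ethnic_group", "unbinned"))
  normalized <- ifelse(!is.na(ci), tables$countries$normalized[ci],
                       ifelse(!is.na(ei), tables$ethnic_groups$normalized[ei],
                              surf))
  out <- data.frame(surface = surf, bin = bin, normalized = normalized,
                    stringsAsFactors = FALSE)
  out <- out[order(out$surface), , drop = FALSE]
  row.names(out) <- NULL
  out
}
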