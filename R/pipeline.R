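# End-to-end driver: screen abstracts, match mentions per sentence, tag
# SNPs/drugs/populations, label sentence polarity, assign categories.

#' Bundle compiled lexicons for a pipeline run
#'
#' @param disease an `hla_disease_lexicon`.
#' @param allele an `hla_allele_lexicon`.
#' @param drug an `hla_drug_lexicon` (optional).
#' @param labels an `hla_label_lexicon`; default the shipped table.
#' @param verbs verb-polarity vector; default the shipped table.
#' @param population_tables from [load_population_tables()].
#' @return list of class `hla_lexicons`.
#' @export
hla_lexicons <- function(disease, allele, drug = NULL,
                         labels = load_label_lexicon(),
                         verbs = load_verb_polarity(),
                         population_tables = load_population_tables()) {
  stopifnot(inherits(disease, "hla_disease_lexicon"),
            inherits(allele, "hla_allele_lexicon"))
  structure(list(disease = disease, allele = allele, drug = drug,
                 labels = labels, verbs = verbs,
                 population_tables = population_tables),
            class = "hla_lexicons")
}

#' Run the full mining pipeline over a corpus
#'
#' Stages: (1) parse MEDLINE XML (unless already-parsed records are given);
#' (2) screen abstracts for joint allele + disease presence in title or
#' text; (3) sentence-split kept abstracts and match allele and disease
#' mentions per sentence; (4) retain co-occurrence sentences and tag drugs
#' (with disease-containment suppression) and SNP rsIDs on them, and
#' populations on whole abstracts; (5) per retained sentence, build the
#' coding vector, stage-1 label, masked text, root verb and final label;
#' (6) assign study categories per abstract.
#'
#' @param corpus MEDLINE XML path/string, or an `hla_abstracts` data frame.
#' @param lexicons an [hla_lexicons()] bundle.
#' @param k_guard carrier-status guard window for [detect_labels()].
#' @param parser optional dependency-parse interface for [root_verb()].
#' @param ner_backend optional population NER backend for
#'   [tag_populations()].
#' @param adr_branch ADR MeSH branch for [categorize_abstract()].
#' @return object of class `hla_mining`: list with `abstracts` (kept
#'   records), `screened_out` (PMIDs dropped at screening), `sentences`
#'   (all sentences of kept abstracts), `mentions`, `labels` (one row per
#'   co-occurrence sentence: `pmid`, `sentence_index`, `stage1`, `verb`,
#'   `verb_class`, `final_label`, `masked`), `snps`, `populations`,
#'   `categories`.
#' @export
mine_corpus <- function(corpus, lexicons, k_guard = 2L, parser = NULL,
                        ner_backend = NULL, adr_branch = "C25") {
  stopifnot(inherits(lexicons, "hla_lexicons"))
  records <- if (inherits(corpus, "hla_abstracts")) corpus else
    parse_medline(corpus)

  keep <- vapply(seq_len(nrow(records)), function(i) {
    screen_abstract(records[i, ], lexicons$allele, lexicons$disease)
  }, logical(1))
  screened_out <- records$pmid[!keep]
  records <- records[keep, , drop = FALSE]
  row.names(records) <- NULL

  sentences <- corpus_sentences(records)

  allele_tab <- .compile_allele_table(lexicons$allele)
  disease_tab <- .compile_disease_table(lexicons$disease)
  am <- .match_corpus(sentences$text, allele_tab, .boundary_class$allele,
                      "allele")
  dm <- .match_corpus(sentences$text, disease_tab, .boundary_class$word,
                      "disease")
  attach_ids <- function(m) {
    if (!nrow(m)) {
      return(cbind(pmid = character(), sentence_index = integer(),
                   .empty_mentions()))
    }
    data.frame(pmid = sentences$pmid[m$.row],
               sentence_index = sentences$index[m$.row],
               m[, setdiff(names(m), ".row"), drop = FALSE],
               stringsAsFactors = FALSE)
  }
  mentions <- rbind(attach_ids(am), attach_ids(dm))

  retained <- filter_cooccurrence_sentences(sentences, mentions)
  rkey <- paste(retained$pmid, retained$index)

  # drugs + SNPs on co-occurrence sentences only
  drug_rows <- list()
  snp_rows <- list()
  if (nrow(retained)) {
    for (i in seq_len(nrow(retained))) {
      key <- rkey[i]
      smen <- mentions[paste(mentions$pmid, mentions$sentence_index) == key, ,
                       drop = FALSE]
      if (!is.null(lexicons$drug) && nrow(lexicons$drug)) {
        dmn <- tag_drugs(retained$text[i], lexicons$drug, smen)
        if (nrow(dmn)) {
          drug_rows[[length(drug_rows) + 1L]] <- data.frame(
            pmid = retained$pmid[i], sentence_index = retained$index[i],
            dmn, stringsAsFactors = FALSE)
        }
      }
      ids <- tag_snps(retained$text[i])
      if (length(ids)) {
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          pmid = retained$pmid[i], sentence_index = retained$index[i],
          rsid = ids, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(drug_rows)) mentions <- rbind(mentions,
                                           do.call(rbind, drug_rows))
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(pmid = character(), sentence_index = integer(),
               rsid = character(), stringsAsFactors = FALSE)
  mentions <- mentions[order(mentions$pmid, mentions$sentence_index,
                             mentions$start, mentions$kind), , drop = FALSE]
  row.names(mentions) <- NULL

  # populations on whole abstracts
  pop_rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- tag_populations(records[i, ], backend = ner_backend,
                         tables = lexicons$population_tables)
    if (nrow(p)) cbind(pmid = records$pmid[i], p, stringsAsFactors = FALSE)
  })
  pop_rows <- pop_rows[!vapply(pop_rows, is.null, logical(1))]
  populations <- if (length(pop_rows)) do.call(rbind, pop_rows) else
    data.frame(pmid = character(), surface = character(), bin = character(),
               normalized = character(), stringsAsFactors = FALSE)
  row.names(populations) <- NULL

  # sentence-level semantics on co-occurrence sentences
  label_rows <- lapply(seq_len(nrow(retained)), function(i) {
    key <- rkey[i]
    smen <- mentions[paste(mentions$pmid, mentions$sentence_index) == key, ,
                     drop = FALSE]
    v <- detect_labels(retained$text[i], lexicons$labels,
                       allele_mentions = smen, k_guard = k_guard)
    stage1 <- code_to_stage1_label(v)
    masked <- mask_entities(retained$text[i], smen)
    rv <- root_verb(masked, lexicons$verbs, parser = parser)
    data.frame(pmid = retained$pmid[i], sentence_index = retained$index[i],
               stage1 = stage1, verb = rv$verb, verb_class = rv$class,
               final_label = annotate_sentence(stage1, rv$class),
               masked = masked, stringsAsFactors = FALSE)
  })
  labels <- if (length(label_rows)) do.call(rbind, label_rows) else
    data.frame(pmid = character(), sentence_index = integer(),
               stage1 = character(), verb = character(),
               verb_class = character(), final_label = character(),
               masked = character(), stringsAsFactors = FALSE)

  # categories per abstract
  cat_rows <- lapply(seq_len(nrow(records)), function(i) {
    pm <- records$pmid[i]
    cats <- categorize_abstract(
      mentions[mentions$pmid == pm, , drop = FALSE],
      sentences[sentences$pmid == pm, , drop = FALSE],
      lexicons$disease, adr_branch = adr_branch)
    data.frame(pmid = pm, categories = paste(cats, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  categories <- if (length(cat_rows)) do.call(rbind, cat_rows) else
    data.frame(pmid = character(), categories = character(),
               stringsAsFactors = FALSE)

  structure(list(abstracts = records, screened_out = screened_out,
                 sentences = sentences, mentions = mentions,
                 labels = labels, snps = snps, populations = populations,
                 categories = categories),
            class = "hla_mining")
}

#' @export
print.hla_mining <- function(x, ...) {
  cat("<hla_mining>\n",
      "  abstracts kept:          ", nrow(x$abstracts),
      " (", length(x$screened_out), " screened out)\n",
      "  co-occurrence sentences: ", nrow(x$labels), "\n",
      "  mentions:                ", nrow(x$mentions), "\n",
      "  SNP tags:                ", nrow(x$snps), "\n", sep = "")
  if (nrow(x$labels)) {
    cat("  final labels:\n")
    print(table(factor(x$labels$final_label, levels = .final_levels)))
  }
  invisible(x)
}
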