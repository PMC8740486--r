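# Deterministic TSV export of every pipeline table, and the inverse reader
# used for round-trip checks.

.write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = TRUE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8", eol = "\n")
}

.collapse_list_col <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

#' Export all annotation tables of a pipeline run
#'
#' Writes one UTF-8 TSV per table — `abstracts`, `sentences`, `mentions`,
#' `sentence_labels`, `snps`, `populations`, `categories`, `summary` —
#' with fixed column order and rows sorted by (`pmid`, `sentence_index`,
#' `start`), so identical runs produce byte-identical files.
#'
#' @param result an `hla_mining` object from [mine_corpus()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
export_tables <- function(result, dir) {
  stopifnot(inherits(result, "hla_mining"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(abstracts = file.path(dir, "abstracts.tsv"),
             sentences = file.path(dir, "sentences.tsv"),
             mentions = file.path(dir, "mentions.tsv"),
             sentence_labels = file.path(dir, "sentence_labels.tsv"),
             snps = file.path(dir, "snps.tsv"),
             populations = file.path(dir, "populations.tsv"),
             categories = file.path(dir, "categories.tsv"),
             summary = file.path(dir, "summary.tsv"))

  ab <- result$abstracts
  ab_flat <- data.frame(pmid = ab$pmid, title = ab$title,
                        abstract = ab$abstract, pub_date = ab$pub_date,
                        journal = ab$journal,
                        article_types = .collapse_list_col(ab$article_types),
                        authors = .collapse_list_col(ab$authors),
                        stringsAsFactors = FALSE)
  ab_flat <- ab_flat[order(ab_flat$pmid), , drop = FALSE]
  .write_tsv(ab_flat, paths["abstracts"])

  sn <- result$sentences[order(result$sentences$pmid,
                               result$sentences$index), , drop = FALSE]
  .write_tsv(sn, paths["sentences"])

  mn <- result$mentions
  mn <- mn[order(mn$pmid, mn$sentence_index, mn$start, mn$kind), ,
           drop = FALSE]
  .write_tsv(mn, paths["mentions"])

  lb <- result$labels[order(result$labels$pmid,
                            result$labels$sentence_index), , drop = FALSE]
  .write_tsv(lb, paths["sentence_labels"])

  sp <- result$snps[order(result$snps$pmid, result$snps$sentence_index,
                          result$snps$rsid), , drop = FALSE]
  .write_tsv(sp, paths["snps"])

  pp <- result$populations[order(result$populations$pmid,
                                 result$populations$surface), , drop = FALSE]
  .write_tsv(pp, paths["populations"])

  ct <- result$categories[order(result$categories$pmid), , drop = FALSE]
  .write_tsv(ct, paths["categories"])

  label_counts <- table(factor(result$labels$final_label,
                               levels = .final_levels))
  cat_counts <- table(factor(unlist(strsplit(result$categories$categories,
                                             ";", fixed = TRUE)),
                             levels = .category_levels))
  summary_df <- data.frame(
    metric = c("n_abstracts", "n_sentences", "n_cooccurrence_sentences",
               "n_mentions", "n_snps", "n_populations",
               paste0("label_", names(label_counts)),
               paste0("category_", names(cat_counts))),
    value = c(nrow(ab), nrow(result$sentences), nrow(result$labels),
              nrow(mn), nrow(sp), nrow(pp),
              as.integer(label_counts), as.integer(cat_counts)),
    stringsAsFactors = FALSE)
  .write_tsv(summary_df, paths["summary"])
  invisible(paths)
}

#' Read exported tables back
#'
#' @param dir directory written by [export_tables()].
#' @return named list of data frames.
#' @export
import_tables <- function(dir) {
  files <- c("abstracts", "sentences", "mentions", "sentence_labels",
             "snps", "populations", "categories", "summary")
  out <- lapply(files, function(f) {
    df <- utils::read.delim(file.path(dir, paste0(f, ".tsv")),
                            stringsAsFactors = FALSE, colClasses = NA,
                            na.strings = character(0))
    if ("pmid" %in% names(df)) df$pmid <- as.character(df$pmid)
    df
  })
  stats::setNames(out, files)
}
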