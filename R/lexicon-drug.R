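# Drug dictionary: SIDER-style drug-name TSV plus supplemental lists
# (allele-frequency and pharmacogenomics resources, local config), with
# case-folded deduplication and source provenance.

#' Build the drug keyword dictionary
#'
#' @param sider_tsv data frame with a `name` column, or a path to a
#'   SIDER-style two-column TSV (`CID<TAB>name`, no header; the last column
#'   is taken as the name).  May be `NULL`.
#' @param extra_lists named list of character vectors of additional drug
#'   names; names are recorded as sources (e.g. `AFND`, `PharmGKB`,
#'   `config`).
#' @return data frame of class `hla_drug_lexicon` with columns `name`
#'   (case-folded), `sources` (`;`-joined), `adr_flag` (`TRUE` for drugs
#'   from side-effect/pharmacogenomics sources, `FALSE` for plain `config`
#'   additions).
#' @export
build_drug_lexicon <- function(sider_tsv = NULL, extra_lists = list()) {
  pools <- list()
  if (!is.null(sider_tsv)) {
    if (is.character(sider_tsv)) {
      df <- utils::read.delim(sider_tsv, header = FALSE,
                              stringsAsFactors = FALSE)
      nm <- df[[ncol(df)]]
    } else {
      nm <- sider_tsv$name
    }
    pools[["SIDER"]] <- nm
  }
  for (src in names(extra_lists)) pools[[src]] <- extra_lists[[src]]
  if (!length(pools) || !length(unlist(pools))) {
    warning("empty drug lexicon")
    out <- data.frame(name = character(), sources = character(),
                      adr_flag = logical(), stringsAsFactors = FALSE)
    class(out) <- c("hla_drug_lexicon", "data.frame")
    return(out)
  }
  long <- do.call(rbind, lapply(names(pools), function(src) {
    nm <- tolower(trimws(pools[[src]]))
    nm <- nm[nzchar(nm)]
    data.frame(name = nm, source = src, stringsAsFactors = FALSE)
  }))
  long <- long[!duplicated(long[, c("name", "source")]), , drop = FALSE]
  agg <- split(long$source, long$name)
  out <- data.frame(
    name = names(agg),
    sources = vapply(agg, function(s) paste(sort(unique(s)), collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE)
  out$adr_flag <- vapply(agg, function(s) any(s != "config"), logical(1))
  out <- out[order(out$name), , drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("hla_drug_lexicon", "data.frame")
  out
}
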