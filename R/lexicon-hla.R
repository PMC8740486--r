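# HLA allele dictionary: canonical colon-delimited names, exhaustive surface
# variants (prefix / star / parenthesized star / collapsed digits), old-name
# history mapping, broad-antigen and haplotype groups, generic keywords.

#' Parse an HLA allele name
#'
#' Accepts current-nomenclature names with or without the `HLA-` prefix,
#' with colon-separated fields (`B*13:01`) or a fully collapsed digit string
#' (`B*1301`, kept as a single field).
#'
#' @param name allele name string.
#' @return list with `gene`, `fields` (character vector) and `canonical`
#'   (`HLA-GENE*F1:F2...`), or `NULL` if the name does not parse.
#' @export
parse_allele_name <- function(name) {
  m <- regmatches(name,
                  regexec("^(?:HLA-)?([A-Za-z]+[0-9]*)(?:\\(\\*\\)|\\*)([0-9]+(?::[0-9]+)*)[NLSCAQ]?$",
                          name, ignore.case = TRUE))[[1]]
  if (!length(m)) {
    # star-less collapsed form like "B1301" or serological "B13"
    m2 <- regmatches(name,
                     regexec("^(?:HLA-)?([A-Za-z]+)([0-9]+)$", name,
                             ignore.case = TRUE))[[1]]
    if (!length(m2)) return(NULL)
    gene <- toupper(m2[2])
    fields <- m2[3]
    return(list(gene = gene, fields = fields,
                canonical = paste0("HLA-", gene, "*", fields)))
  }
  gene <- toupper(m[2])
  fields <- strsplit(m[3], ":", fixed = TRUE)[[1]]
  list(gene = gene, fields = fields,
       canonical = paste0("HLA-", gene, "*", paste(fields, collapse = ":")))
}

# All lower-cased surface variants of gene + fields: with/without "HLA-",
# star as "*", "(*)" or absent, fields joined by ":" or fully collapsed.
allele_surface_variants <- function(gene, fields) {
  g <- tolower(gene)
  seps <- unique(c(paste(fields, collapse = ":"),
                   paste(fields, collapse = "")))
  out <- character(0)
  for (fs in seps) {
    for (star in c("*", "(*)", "")) {
      for (prefix in c("hla-", "")) {
        out <- c(out, paste0(prefix, g, star, fs))
      }
    }
  }
  unique(out)
}

.add_surface <- function(env, surface, canonical) {
  cur <- env[[surface]]
  env[[surface]] <- unique(c(cur, canonical))
  invisible(NULL)
}

#' Build the HLA allele dictionary and surface map
#'
#' From an IMGT-dialect allele list (CSV with columns `AlleleID`, `Name`,
#' names without the `HLA-` prefix), every allele contributes a canonical
#' entry for its exact name and, when it has more than two fields, for its
#' two-field truncation; each entry generates the full surface-variant set
#' (`hla-b*13:01`, `hla-b*1301`, `b*1301`, `b(*)1301`, `b1301`, ...).
#' History rows map old names to current canonicals; rows whose current name
#' is empty are retired and excluded from matching.  Group config adds
#' broad-antigen and haplotype entries (several candidate canonicals per
#' surface) and generic keywords (`HLA class I`, `HLA class II`,
#' `HLA linked`, `HLA associated`).
#'
#' @param allele_list data frame (`AlleleID`, `Name`) or CSV path
#'   (`#`-comment lines ignored).
#' @param history optional data frame (`old`, `current`) or CSV path.
#' @param groups optional list (or YAML path) with elements `broad_antigen`
#'   (name -> candidate canonicals), `haplotype` (name -> member
#'   canonicals), `generic` (character vector).
#' @return object of class `hla_allele_lexicon`: list with `entries`
#'   (data frame `canonical`, `gene`, `fields`, `category`), `surfaces`
#'   (environment: surface -> candidate canonicals) and `retired`.
#' @export
build_hla_lexicon <- function(allele_list, history = NULL, groups = NULL) {
  if (is.character(allele_list)) {
    allele_list <- utils::read.csv(allele_list, comment.char = "#",
                                   stringsAsFactors = FALSE)
  }
  stopifnot("Name" %in% names(allele_list))
  if (is.character(history)) {
    history <- utils::read.csv(history, comment.char = "#",
                               stringsAsFactors = FALSE)
  }
  if (is.character(groups)) groups <- yaml::read_yaml(groups)

  surfaces <- new.env(parent = emptyenv())
  entries <- list()
  seen <- new.env(parent = emptyenv())
  add_entry <- function(canonical, gene, fields, category) {
    key <- paste0(category, "\r", canonical)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    entries[[length(entries) + 1L]] <<- data.frame(
      canonical = canonical, gene = gene,
      fields = paste(fields, collapse = ":"), category = category,
      stringsAsFactors = FALSE)
  }

  for (name in allele_list$Name) {
    p <- parse_allele_name(name)
    if (is.null(p)) {
      warning("unparseable allele name skipped: ", name)
      next
    }
    targets <- list(p)
    if (length(p$fields) > 2L) {
      f2 <- p$fields[1:2]
      targets <- c(targets, list(list(
        gene = p$gene, fields = f2,
        canonical = paste0("HLA-", p$gene, "*", paste(f2, collapse = ":")))))
    }
    for (t in targets) {
      add_entry(t$canonical, t$gene, t$fields, "current")
      for (s in allele_surface_variants(t$gene, t$fields)) {
        .add_surface(surfaces, s, t$canonical)
      }
    }
  }

  retired <- character(0)
  if (!is.null(history) && nrow(history)) {
    stopifnot(all(c("old", "current") %in% names(history)))
    for (i in seq_len(nrow(history))) {
      old <- history$old[i]
      cur <- history$current[i]
      if (is.na(cur) || !nzchar(cur)) {
        retired <- c(retired, old)
        next
      }
      pc <- parse_allele_name(cur)
      if (is.null(pc)) {
        warning("history row with unparseable current name skipped: ", cur)
        next
      }
      add_entry(pc$canonical, pc$gene, pc$fields, "old-mapped")
      po <- parse_allele_name(old)
      if (!is.null(po)) {
        for (s in allele_surface_variants(po$gene, po$fields)) {
          .add_surface(surfaces, s, pc$canonical)
        }
      } else {
        .add_surface(surfaces, tolower(old), pc$canonical)
        .add_surface(surfaces, paste0("hla-", tolower(old)), pc$canonical)
      }
    }
  }

  if (!is.null(groups)) {
    for (nm in names(groups$broad_antigen)) {
      cand <- groups$broad_antigen[[nm]]
      if (length(cand) < 2L)
        warning("broad-antigen group ", nm, " has fewer than 2 candidates")
      add_entry(nm, sub("[0-9]+$", "", toupper(nm)),
                sub("^[A-Za-z]+", "", nm), "broad-antigen")
      for (s in unique(c(tolower(nm), paste0("hla-", tolower(nm))))) {
        for (cc in cand) .add_surface(surfaces, s, cc)
      }
    }
    for (nm in names(groups$haplotype)) {
      members <- groups$haplotype[[nm]]
      add_entry(nm, NA_character_, "", "haplotype")
      for (s in unique(c(tolower(nm), paste0("hla-", tolower(nm))))) {
        for (cc in members) .add_surface(surfaces, s, cc)
      }
    }
    for (g in groups$generic) {
      add_entry(g, NA_character_, "", "generic")
      .add_surface(surfaces, tolower(g), g)
      # variant without the "HLA " prefix is too generic; keep as-is only
    }
  }

  entries <- do.call(rbind, entries)
  row.names(entries) <- NULL
  structure(list(entries = entries, surfaces = surfaces, retired = retired,
                 groups = groups, cache = new.env(parent = emptyenv())),
            class = "hla_allele_lexicon")
}

#' @export
print.hla_allele_lexicon <- function(x, ...) {
  cat("<hla_allele_lexicon> ", nrow(x$entries), " entries, ",
      length(ls(x$surfaces)), " surfaces, ",
      length(x$retired), " retired\n", sep = "")
  invisible(x)
}

#' Normalize an allele surface form to canonical name(s)
#'
#' Looks the surface up in the lexicon's surface map (case-insensitive; the
#' special-character-stripped form is tried too).  Canonical names map to
#' themselves, so the function is idempotent.  Broad-antigen and haplotype
#' surfaces return all candidate canonicals with attribute
#' `ambiguous = TRUE`.
#'
#' @param lexicon an `hla_allele_lexicon`.
#' @param surface text of an allele mention.
#' @return character vector of canonical names (singleton when unambiguous)
#'   with attribute `ambiguous`.
#' @export
normalize_allele <- function(lexicon, surface) {
  stopifnot(inherits(lexicon, "hla_allele_lexicon"))
  s <- tolower(surface)
  hit <- lexicon$surfaces[[s]]
  if (is.null(hit)) hit <- lexicon$surfaces[[preprocess_variants(s)$b]]
  if (is.null(hit)) stop("unknown allele surface: ", surface, call. = FALSE)
  hit <- sort(hit)
  attr(hit, "ambiguous") <- length(hit) > 1L
  hit
}

#' Collapse an allele name to its two-digit group
#'
#' Keeps the locus and the first numeric field only:
#' `HLA-B*13:01` -> `HLA-B*13`.  Generic keywords and haplotypes are not
#' collapsible.
#'
#' @param canonical character vector of canonical allele names.
#' @return character vector of two-digit group names.
#' @export
collapse_two_digit <- function(canonical) {
  vapply(canonical, function(x) {
    p <- parse_allele_name(x)
    if (is.null(p)) stop("not collapsible: ", x, call. = FALSE)
    paste0("HLA-", p$gene, "*", p$fields[1])
  }, character(1), USE.NAMES = FALSE)
}

# All surfaces registered in the lexicon (sorted, for matcher compilation).
allele_surfaces <- function(lexicon) sort(ls(lexicon$surfaces))
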