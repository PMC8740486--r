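# Disease dictionary: MeSH descriptor keywords from an MRCONSO.RRF-dialect
# concept table, widened with plural/lemma variants, plus the descriptor
# tree-number hierarchy used for level-one mapping and study categories.

# MeSH top-level branch letters -> root ("level-zero") labels.
.mesh_roots <- c(
  A = "Anatomy", B = "Organisms", C = "Diseases",
  D = "Chemicals and Drugs",
  E = "Analytical, Diagnostic and Therapeutic Techniques and Equipment",
  F = "Psychiatry and Psychology", G = "Phenomena and Processes",
  H = "Disciplines and Occupations",
  I = "Anthropology, Education, Sociology, and Social Phenomena",
  J = "Technology, Industry, and Agriculture", K = "Humanities",
  L = "Information Science", M = "Named Groups", N = "Health Care",
  V = "Publication Characteristics", Z = "Geographicals"
)

# Descriptor (term-type) codes retained in the dictionary.  DEV (Descriptor
# Entry Version) keywords are truncated forms ("abdominal inj") and are
# excluded.
.kept_descriptor_types <- c("ET", "MH", "PEP", "DSV", "PM")

#' Read an MRCONSO.RRF-dialect concept file
#'
#' Pipe-delimited UMLS concept rows.  Only the keyword string, term type and
#' source descriptor ID columns are used; their 1-based indices are
#' configurable for other dialects of the format.  When a source-vocabulary
#' column index is given, rows are restricted to MeSH (`SAB == "MSH"`).
#'
#' @param path file path.
#' @param col_str,col_tty,col_sdui,col_sab 1-based column indices of the
#'   keyword string, term type, MeSH descriptor ID and source vocabulary
#'   (set `col_sab = NA` to skip source filtering).
#' @return data frame with columns `keyword`, `descriptor_type`, `mesh_id`.
#' @export
read_mrconso <- function(path, col_str = 15L, col_tty = 13L, col_sdui = 11L,
                         col_sab = 12L) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "|", fixed = TRUE)
  pick <- function(p, i) if (length(p) >= i) p[[i]] else NA_character_
  out <- data.frame(
    keyword = vapply(parts, pick, character(1), col_str),
    descriptor_type = vapply(parts, pick, character(1), col_tty),
    mesh_id = vapply(parts, pick, character(1), col_sdui),
    stringsAsFactors = FALSE)
  if (!is.na(col_sab)) {
    sab <- vapply(parts, pick, character(1), col_sab)
    out <- out[!is.na(sab) & sab == "MSH", , drop = FALSE]
  }
  row.names(out) <- NULL
  out
}

#' Build the MeSH descriptor hierarchy
#'
#' @param tree_table data frame (or TSV path) with columns `mesh_id`,
#'   `label`, `tree_number` (one row per tree number).
#' @return object of class `mesh_hierarchy`: list with `nodes` (per
#'   descriptor: label + tree numbers), `tree` (the input table) and `roots`
#'   (branch letter to level-zero label map).
#' @export
mesh_hierarchy <- function(tree_table) {
  if (is.character(tree_table)) {
    tree_table <- utils::read.delim(tree_table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("mesh_id", "label", "tree_number") %in% names(tree_table)))
  nodes <- split(tree_table, tree_table$mesh_id)
  nodes <- lapply(nodes, function(d) {
    list(label = d$label[1], tree_numbers = d$tree_number)
  })
  structure(list(nodes = nodes, tree = tree_table, roots = .mesh_roots),
            class = "mesh_hierarchy")
}

#' Ancestor of a tree number at a given level
#'
#' Level 0 is the root form (the MeSH branch letter, e.g. `C` = Diseases);
#' level 1 is the top-level descriptor (e.g. `C20`); higher levels keep more
#' tree segments.
#'
#' @param hier a [mesh_hierarchy()] object.
#' @param tree_number a tree code such as `"C20.111.258"`.
#' @param level non-negative integer.
#' @return list with `tree_prefix`, `label` and (for level >= 1) `mesh_id`;
#'   `NULL` when the prefix has no descriptor in the table.
#' @export
mesh_ancestor <- function(hier, tree_number, level) {
  stopifnot(inherits(hier, "mesh_hierarchy"), level >= 0L)
  if (level == 0L) {
    letter <- substr(tree_number, 1L, 1L)
    lab <- hier$roots[[letter]]
    if (is.null(lab)) return(NULL)
    return(list(tree_prefix = letter, label = lab, mesh_id = NA_character_))
  }
  segs <- strsplit(tree_number, ".", fixed = TRUE)[[1]]
  if (length(segs) < level) return(NULL)
  prefix <- paste(segs[seq_len(level)], collapse = ".")
  hit <- hier$tree[hier$tree$tree_number == prefix, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  list(tree_prefix = prefix, label = hit$label[1], mesh_id = hit$mesh_id[1])
}

#' Build the disease keyword dictionary
#'
#' Retains MeSH keyword rows of descriptor types ET, MH, PEP, DSV and PM
#' (Entry Term, Main Heading, Preferred Entry term, Descriptor Sort Version,
#' Machine Permutation); DEV rows are excluded and rows with any other type
#' are skipped with a warning.  Each retained keyword also emits a plural
#' and a lemmatized (singular) variant pointing at the same MeSH ID, so
#' surface variation in abstracts does not cost recall.
#'
#' @param concept_rows data frame from [read_mrconso()] (or a path to an
#'   MRCONSO-dialect file).
#' @param tree_table tree-number table or path, see [mesh_hierarchy()].
#' @param lemmatizer function mapping a word to its lemma; default
#'   [singularize()].
#' @return object of class `hla_disease_lexicon`: list with `entries`
#'   (data frame `surface`, `mesh_id`, `descriptor_type`, `unrooted`) and
#'   `hierarchy` (a `mesh_hierarchy`).
#' @export
build_disease_lexicon <- function(concept_rows, tree_table,
                                  lemmatizer = singularize) {
  if (is.character(concept_rows)) concept_rows <- read_mrconso(concept_rows)
  hier <- if (inherits(tree_table, "mesh_hierarchy")) tree_table else
    mesh_hierarchy(tree_table)
  rows <- concept_rows
  unknown <- setdiff(unique(rows$descriptor_type),
                     c(.kept_descriptor_types, "DEV"))
  if (length(unknown)) {
    warning("skipping rows with unknown descriptor type(s): ",
            paste(unknown, collapse = ", "))
  }
  rows <- rows[rows$descriptor_type %in% .kept_descriptor_types, ,
               drop = FALSE]
  rows <- rows[nzchar(rows$keyword) & nzchar(rows$mesh_id), , drop = FALSE]

  base <- data.frame(surface = tolower(rows$keyword),
                     mesh_id = rows$mesh_id,
                     descriptor_type = rows$descriptor_type,
                     stringsAsFactors = FALSE)
  variants <- list()
  for (i in seq_len(nrow(base))) {
    s <- base$surface[i]
    pl <- pluralize(s)
    if (!is.na(pl) && !identical(pl, s)) {
      variants[[length(variants) + 1L]] <- data.frame(
        surface = pl, mesh_id = base$mesh_id[i],
        descriptor_type = "plural-variant", stringsAsFactors = FALSE)
    }
    parts <- strsplit(s, " ", fixed = TRUE)[[1]]
    parts[length(parts)] <- lemmatizer(parts[length(parts)])
    lem <- paste(parts, collapse = " ")
    if (!identical(lem, s)) {
      variants[[length(variants) + 1L]] <- data.frame(
        surface = lem, mesh_id = base$mesh_id[i],
        descriptor_type = "lemma-variant", stringsAsFactors = FALSE)
    }
  }
  entries <- rbind(base, if (length(variants)) do.call(rbind, variants))
  # a surface generated as a variant may duplicate an explicit keyword row;
  # explicit rows (listed first) win
  entries <- entries[!duplicated(entries[, c("surface", "mesh_id")]), ,
                     drop = FALSE]
  entries$unrooted <- !(entries$mesh_id %in% names(hier$nodes))
  entries <- entries[order(entries$surface, entries$mesh_id), , drop = FALSE]
  row.names(entries) <- NULL
  structure(list(entries = entries, hierarchy = hier,
                 cache = new.env(parent = emptyenv())),
            class = "hla_disease_lexicon")
}

#' @export
print.hla_disease_lexicon <- function(x, ...) {
  cat("<hla_disease_lexicon> ", nrow(x$entries), " surfaces, ",
      length(unique(x$entries$mesh_id)), " MeSH descriptors\n", sep = "")
  invisible(x)
}

#' Normalize a matched disease keyword to its MeSH descriptor
#'
#' @param lexicon an `hla_disease_lexicon`.
#' @param surface a keyword present in the lexicon (case-insensitive).
#' @return list with `mesh_id`, `level_one` (label of the top-level
#'   ancestor, `NA` if unrooted) and `level_zero` (root-form label).
#' @export
normalize_disease <- function(lexicon, surface) {
  stopifnot(inherits(lexicon, "hla_disease_lexicon"))
  s <- tolower(surface)
  hit <- lexicon$entries[lexicon$entries$surface == s, , drop = FALSE]
  if (!nrow(hit)) stop("unknown disease keyword: ", surface, call. = FALSE)
  mesh_id <- sort(unique(hit$mesh_id))[1]
  node <- lexicon$hierarchy$nodes[[mesh_id]]
  level_one <- NA_character_
  level_zero <- NA_character_
  if (!is.null(node) && length(node$tree_numbers)) {
    tn <- sort(node$tree_numbers)[1]
    a1 <- mesh_ancestor(lexicon$hierarchy, tn, 1L)
    a0 <- mesh_ancestor(lexicon$hierarchy, tn, 0L)
    if (!is.null(a1)) level_one <- a1$label
    if (!is.null(a0)) level_zero <- a0$label
  }
  list(mesh_id = mesh_id, level_one = level_one, level_zero = level_zero)
}

# Tree numbers for a MeSH descriptor, character(0) when unrooted.
mesh_tree_numbers <- function(lexicon, mesh_id) {
  node <- lexicon$hierarchy$nodes[[mesh_id]]
  if (is.null(node)) character(0) else node$tree_numbers
}
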