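# Seeded miniature inputs with planted ground truth: lexicon source files
# in the external dialects (IMGT-style allele list + history, MRCONSO-style
# concepts, MeSH tree table, SIDER-style drug TSV, group config) and a
# PubMed-dialect XML corpus built from sentence templates whose intended
# mentions, labels and categories are known exactly by construction.

# ---- planted entity pools (all covered by generate_lexicon_sources()) ----

.fx_alleles <- list(
  "HLA-B*13:01" = c("HLA-B*13:01", "HLA-B*1301", "B*1301", "B(*)1301",
                    "B1301"),
  "HLA-B*57:01" = c("HLA-B*57:01", "B*57:01", "B*5701", "HLA-B*5701"),
  "HLA-B*15:02" = c("HLA-B*15:02", "B*15:02", "B*1502"),
  "HLA-A*31:01" = c("HLA-A*31:01", "A*31:01", "A*3101"),
  "HLA-A*24:02" = c("HLA-A*24:02", "A*24:02", "A(*)2402"),
  "HLA-DRB1*15:01" = c("HLA-DRB1*15:01", "DRB1*15:01", "DRB1*1501"),
  "HLA-DQB1*06:02" = c("HLA-DQB1*06:02", "DQB1*0602"),
  "HLA-B*08:01" = c("HLA-B*08:01", "B*0801")
)

.fx_diseases <- data.frame(
  surface = c("multiple sclerosis", "rheumatoid arthritis",
              "type 1 diabetes", "melanoma", "psoriasis",
              "ankylosing spondylitis", "hepatitis B"),
  mesh_id = c("D009103", "D001172", "D003922", "D008545", "D011565",
              "D013167", "D006509"),
  stringsAsFactors = FALSE)

.fx_adr <- data.frame(
  drug = c("carbamazepine", "carbamazepine", "dapsone", "allopurinol"),
  surface = c("Stevens-Johnson syndrome", "Stevens Johnson syndrome",
              "drug hypersensitivity", "drug-induced liver injury"),
  mesh_id = c("D013262", "D013262", "D004342", "D056486"),
  # diseases already naming "-induced" use the exposure-style template
  exposure = c(FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

.fx_pops <- data.frame(
  surface = c("Japanese", "Chinese", "Indian", "Italian", "Korean",
              "Han", "European"),
  bin = c(rep("country", 5), "ethnic_group", "ethnic_group"),
  normalized = c("Japanese", "Chinese", "Indian", "Italian", "Korean",
                 "Han", "European"),
  stringsAsFactors = FALSE)

.fx_rsids <- c("rs9277535", "rs2395029", "rs3135388", "rs660895",
               "rs9271366", "rs1063635")

# ---- lexicon source files -----------------------------------------------

.mrconso_row <- function(str, tty, sdui) {
  f <- rep("", 18)
  f[1] <- paste0("C", substr(sdui, 2, 8))  # fabricated concept id
  f[2] <- "ENG"
  f[11] <- sdui
  f[12] <- "MSH"
  f[13] <- tty
  f[15] <- str
  paste(f, collapse = "|")
}

#' Write miniature lexicon source files
#'
#' Emits, under `dir`: `alleles.csv` (IMGT-dialect `AlleleID,Name`),
#' `allele_history.csv` (`old,current`; one retired row with empty
#' current), `mesh_concepts.rrf` (MRCONSO-dialect, including one DEV row to
#' exercise exclusion), `mesh_tree.tsv`, `drugs.tsv` (SIDER-dialect,
#' no header), `drug_extras.yaml` (supplemental drug lists) and
#' `allele_groups.yaml` (broad-antigen / haplotype / generic config).
#' All files parse with the lexicon builders and cover every entity the
#' corpus generator can plant.
#'
#' @param dir output directory (created if missing).
#' @return named character vector of file paths.
#' @export
generate_lexicon_sources <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(alleles = file.path(dir, "alleles.csv"),
             history = file.path(dir, "allele_history.csv"),
             concepts = file.path(dir, "mesh_concepts.rrf"),
             tree = file.path(dir, "mesh_tree.tsv"),
             drugs = file.path(dir, "drugs.tsv"),
             drug_extras = file.path(dir, "drug_extras.yaml"),
             groups = file.path(dir, "allele_groups.yaml"))

  alleles <- c(
    "AlleleID,Name",
    "HLA00001,A*01:01:01:01", "HLA00043,A*23:01:01",
    "HLA00050,A*24:02:01:01", "HLA02301,A*31:01:02",
    "HLA00132,B*08:01:01", "HLA00152,B*13:01:01",
    "HLA00162,B*15:02:01", "HLA00334,B*38:02:01",
    "HLA00381,B*54:01:01", "HLA00386,B*55:01:01",
    "HLA00392,B*56:01:01", "HLA00401,B*57:01:01",
    "HLA00664,DRB1*03:01:01", "HLA00865,DRB1*15:01:01",
    "HLA00876,DRB1*16:01:01", "HLA00622,DQA1*02:01",
    "HLA00638,DQA1*03:02", "HLA00646,DQB1*06:02:01")
  writeLines(alleles, paths["alleles"])

  history <- c("old,current",
               "B*1301,B*13:01",
               "A*2402,A*24:02",
               "DR15,DRB1*15:01",
               "Cw*0602,")  # deleted allele with no successor -> retired
  writeLines(history, paths["history"])

  concepts <- c(
    .mrconso_row("Neoplasms", "MH", "D009369"),
    .mrconso_row("tumor", "ET", "D009369"),
    .mrconso_row("tumour", "ET", "D009369"),
    .mrconso_row("cancer", "ET", "D009369"),
    .mrconso_row("malignancy", "ET", "D009369"),
    .mrconso_row("neoplasm", "PEP", "D009369"),
    .mrconso_row("Melanoma", "MH", "D008545"),
    .mrconso_row("Arthritis, Rheumatoid", "PM", "D001172"),
    .mrconso_row("rheumatoid arthritis", "ET", "D001172"),
    .mrconso_row("Multiple Sclerosis", "MH", "D009103"),
    .mrconso_row("Diabetes Mellitus", "MH", "D003920"),
    .mrconso_row("type 1 diabetes", "ET", "D003922"),
    .mrconso_row("type 1 diabetes mellitus", "ET", "D003922"),
    .mrconso_row("insulin dependent diabetes mellitus", "ET", "D003922"),
    .mrconso_row("juvenile-onset diabetes", "ET", "D003922"),
    .mrconso_row("Diabetes Mellitus, Type 1", "DSV", "D003922"),
    .mrconso_row("Stevens-Johnson Syndrome", "MH", "D013262"),
    .mrconso_row("Graft vs Host Disease", "MH", "D006086"),
    .mrconso_row("graft versus host disease", "ET", "D006086"),
    .mrconso_row("graft-versus-host disease", "ET", "D006086"),
    .mrconso_row("Proteinuria", "MH", "D011507"),
    .mrconso_row("Bone Marrow Transplantation", "MH", "D016026"),
    .mrconso_row("drug-induced liver injury", "ET", "D056486"),
    .mrconso_row("Drug Hypersensitivity", "MH", "D004342"),
    .mrconso_row("Hepatitis B", "MH", "D006509"),
    .mrconso_row("ankylosing spondylitis", "ET", "D013167"),
    .mrconso_row("Spondylitis, Ankylosing", "PM", "D013167"),
    .mrconso_row("Psoriasis", "MH", "D011565"),
    .mrconso_row("Abdominal Injuries", "MH", "D000007"),
    .mrconso_row("abdominal inj", "DEV", "D000007"))
  writeLines(concepts, paths["concepts"])

  tree <- c(
    "mesh_id\tlabel\ttree_number",
    "D007239\tInfections\tC01",
    "D009369\tNeoplasms\tC04",
    "D009140\tMusculoskeletal Diseases\tC05",
    "D004066\tDigestive System Diseases\tC06",
    "D009422\tNervous System Diseases\tC10",
    "D017437\tSkin and Connective Tissue Diseases\tC17",
    "D009750\tNutritional and Metabolic Diseases\tC18",
    "D004700\tEndocrine System Diseases\tC19",
    "D007154\tImmune System Diseases\tC20",
    "D013568\tPathological Conditions, Signs and Symptoms\tC23",
    "D064419\tChemically-Induced Disorders\tC25",
    "D014947\tWounds and Injuries\tC26",
    "D013514\tSurgical Procedures, Operative\tE04",
    "D008545\tMelanoma\tC04.557.465",
    "D001172\tArthritis, Rheumatoid\tC05.550.114",
    "D001172\tArthritis, Rheumatoid\tC20.111.199",
    "D009103\tMultiple Sclerosis\tC10.114.375.500",
    "D009103\tMultiple Sclerosis\tC20.111.258.500",
    "D003920\tDiabetes Mellitus\tC18.452.394.750",
    "D003920\tDiabetes Mellitus\tC19.246",
    "D003922\tDiabetes Mellitus, Type 1\tC18.452.394.750.124",
    "D003922\tDiabetes Mellitus, Type 1\tC19.246.267",
    "D003922\tDiabetes Mellitus, Type 1\tC20.111.327",
    "D013262\tStevens-Johnson Syndrome\tC17.800.229.400",
    "D013262\tStevens-Johnson Syndrome\tC25.100.468",
    "D006086\tGraft vs Host Disease\tC20.452.274",
    "D011507\tProteinuria\tC23.888.942",
    "D016026\tBone Marrow Transplantation\tE04.936.225",
    "D056486\tChemical and Drug Induced Liver Injury\tC06.552.195",
    "D056486\tChemical and Drug Induced Liver Injury\tC25.100.562",
    "D004342\tDrug Hypersensitivity\tC20.543.206",
    "D004342\tDrug Hypersensitivity\tC25.100.470",
    "D006509\tHepatitis B\tC01.925.440",
    "D013167\tSpondylitis, Ankylosing\tC05.116.900.853",
    "D011565\tPsoriasis\tC17.800.859.675",
    "D000007\tAbdominal Injuries\tC26.017")
  writeLines(tree, paths["tree"])

  drugs <- c("CID100002244\tcarbamazepine",
             "CID100441300\tabacavir",
             "CID100002094\tallopurinol",
             "CID100002955\tdapsone",
             "CID100003715\tinsulin",
             "CID100006062\tazathioprine")
  writeLines(drugs, paths["drugs"])

  yaml::write_yaml(list(AFND = c("carbimazole", "methimazole"),
                        PharmGKB = c("phenytoin", "nevirapine",
                                     "carbamazepine")),
                   paths["drug_extras"])

  yaml::write_yaml(list(
    broad_antigen = list(
      B22 = c("HLA-B*54:01", "HLA-B*55:01", "HLA-B*56:01"),
      A9 = c("HLA-A*23:01", "HLA-A*24:02"),
      DR2 = c("HLA-DRB1*15:01", "HLA-DRB1*16:01")),
    haplotype = list(
      `A1-B8-DR3` = c("HLA-A*01:01", "HLA-B*08:01", "HLA-DRB1*03:01")),
    generic = c("HLA class I", "HLA class II", "HLA linked",
                "HLA associated")), paths["groups"])
  paths
}

#' Build the lexicon bundle from generated source files
#'
#' Convenience wrapper: [generate_lexicon_sources()] then the three
#' builders, returning an [hla_lexicons()] bundle.
#'
#' @param dir directory for the source files (default a temporary one).
#' @return an `hla_lexicons` bundle.
#' @export
fixture_lexicons <- function(dir = tempfile("lexsrc")) {
  paths <- generate_lexicon_sources(dir)
  extras <- yaml::read_yaml(paths["drug_extras"])
  hla_lexicons(
    disease = build_disease_lexicon(paths[["concepts"]], paths[["tree"]]),
    allele = build_hla_lexicon(paths[["alleles"]], paths[["history"]],
                               paths[["groups"]]),
    drug = build_drug_lexicon(paths[["drugs"]], extras))
}

# ---- corpus generation ---------------------------------------------------

#' Specify a synthetic corpus
#'
#' Per-class abstract counts for the sentence templates (each abstract has
#' a filler sentence and one template sentence whose intended mentions and
#' labels are recorded as ground truth), plus incomplete records for
#' testing the parser's skip log.  The seed fixes all sampling, so a given
#' spec always generates the same corpus.
#'
#' @param n_positive,n_negative,n_negation,n_investigatory,n_complex,n_others
#'   abstracts per polarity template class.
#' @param n_adr drug-induced disease abstracts (category Therapeutics/ADR).
#' @param n_transplant graft-versus-host / transplantation abstracts.
#' @param n_signs signs-and-symptoms abstracts.
#' @param n_insulin abstracts planting `insulin dependent diabetes
#'   mellitus` to exercise drug false-positive suppression.
#' @param n_incomplete records lacking an abstract (skipped by the parser).
#' @param seed integer random seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_positive = 5L, n_negative = 3L, n_negation = 2L,
                         n_investigatory = 2L, n_complex = 2L,
                         n_others = 2L, n_adr = 2L, n_transplant = 2L,
                         n_signs = 2L, n_insulin = 1L, n_incomplete = 0L,
                         seed = 1L) {
  spec <- list(n_positive = n_positive, n_negative = n_negative,
               n_negation = n_negation, n_investigatory = n_investigatory,
               n_complex = n_complex, n_others = n_others, n_adr = n_adr,
               n_transplant = n_transplant, n_signs = n_signs,
               n_insulin = n_insulin, n_incomplete = n_incomplete,
               seed = as.integer(seed))
  stopifnot(all(vapply(spec, function(x) length(x) == 1L && x >= 0,
                       logical(1))))
  class(spec) <- "fixture_spec"
  spec
}

.fx_journals <- c("Tissue Antigens", "Human Immunology",
                  "International Journal of Immunogenetics")

# One template instance: text plus planted truth.
.fx_template <- function(class, draw) {
  A <- draw$allele_surface
  Acan <- draw$allele_canonical
  D <- draw$disease_surface
  P <- draw$pop
  RS <- if (is.na(draw$rsid)) "" else paste0(" (", draw$rsid, ")")
  mention <- function(kind, surface, canonical) {
    data.frame(kind = kind, surface = surface, canonical = canonical,
               stringsAsFactors = FALSE)
  }
  base <- list(mentions = rbind(mention("allele", A, Acan),
                                mention("disease", D, draw$disease_mesh)),
               categories = "Diseases")
  out <- switch(class,
    positive = c(list(
      text = sprintf("%s was significantly associated with %s in %s patients%s.",
                     A, D, P, RS),
      stage1 = "positive", final = "Positive"), base),
    negative = c(list(
      text = sprintf("%s protected against %s in %s individuals.", A, D, P),
      stage1 = "negative", final = "Negative"), base),
    negation = c(list(
      text = sprintf("No association between %s and %s was observed in %s subjects.",
                     A, D, P),
      stage1 = "negation", final = "Ambiguous"), base),
    investigatory = c(list(
      text = sprintf("To investigate the role of %s in %s, we genotyped %s patients.",
                     A, D, P),
      stage1 = "others", final = "Investigatory"), base),
    complex = list(
      text = sprintf("%s was strongly associated with %s but protected against %s in %s patients.",
                     A, D, draw$disease2_surface, P),
      stage1 = "complex", final = "Complex",
      mentions = rbind(mention("allele", A, Acan),
                       mention("disease", D, draw$disease_mesh),
                       mention("disease", draw$disease2_surface,
                               draw$disease2_mesh)),
      categories = "Diseases"),
    others = c(list(
      text = sprintf("%s was genotyped in %s patients with %s.", A, P, D),
      stage1 = "others", final = "Others"), base),
    adr = {
      drug_cap <- paste0(toupper(substr(draw$drug, 1, 1)),
                         substring(draw$drug, 2))
      txt <- if (draw$exposure) {
        sprintf("%s exposure was significantly associated with %s in %s patients carrying %s%s.",
                drug_cap, D, P, A, RS)
      } else {
        sprintf("%s-induced %s was significantly associated with %s in %s patients%s.",
                drug_cap, D, A, P, RS)
      }
      list(text = txt, stage1 = "positive", final = "Positive",
           mentions = rbind(mention("allele", A, Acan),
                            mention("disease", D, draw$disease_mesh),
                            mention("drug", drug_cap, draw$drug)),
           categories = "Diseases;TherapeuticsADR")
    },
    transplant = list(
      text = sprintf("%s mismatch increased graft versus host disease in patients undergoing bone marrow transplantation.",
                     A),
      stage1 = "positive", final = "Positive",
      mentions = rbind(mention("allele", A, Acan),
                       mention("disease", "graft versus host disease",
                               "D006086"),
                       mention("disease", "bone marrow transplantation",
                               "D016026")),
      categories = "Transplantation"),
    signs = list(
      text = sprintf("%s carriers presented with proteinuria in the %s population.",
                     A, P),
      stage1 = "others", final = "Others",
      mentions = rbind(mention("allele", A, Acan),
                       mention("disease", "proteinuria", "D011507")),
      categories = "SignsSymptoms"),
    insulin = list(
      text = sprintf("%s was genotyped in patients with insulin dependent diabetes mellitus.",
                     A),
      stage1 = "others", final = "Others",
      mentions = rbind(mention("allele", A, Acan),
                       mention("disease",
                               "insulin dependent diabetes mellitus",
                               "D003922")),
      categories = "Diseases"),
    stop("unknown template class: ", class))
  out
}

#' Generate a PubMed-dialect XML corpus with planted ground truth
#'
#' Every abstract is a filler sentence plus one slot-filled template
#' sentence drawn from the class pools in `spec`; the planted allele
#' surface variant, disease keyword, drug, rsID and population — and the
#' intended coding-vector stage-1 label, final sentence label and abstract
#' categories — are recorded in truth tables written next to the XML.
#' Incomplete records (no abstract) are appended for parser skip-log
#' testing.  All sampling is driven by `spec$seed`, so the output is
#' byte-identical across runs.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if missing).
#' @return list with `xml` (corpus path), `truth` (list of data frames:
#'   `abstracts`, `sentences`, `mentions`, `snps`, `populations`) and
#'   `paths` of the truth TSVs.
#' @export
generate_corpus <- function(spec, dir = tempfile("corpus")) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)
  classes <- rep(c("positive", "negative", "negation", "investigatory",
                   "complex", "others", "adr", "transplant", "signs",
                   "insulin"),
                 c(spec$n_positive, spec$n_negative, spec$n_negation,
                   spec$n_investigatory, spec$n_complex, spec$n_others,
                   spec$n_adr, spec$n_transplant, spec$n_signs,
                   spec$n_insulin))
  n <- length(classes)
  truth_abs <- list(); truth_sent <- list(); truth_men <- list()
  truth_snp <- list(); truth_pop <- list()
  articles <- list()

  for (i in seq_len(n)) {
    cls <- classes[i]
    pmid <- sprintf("%d", 1000000L + i)
    ai <- sample(length(.fx_alleles), 1L)
    di <- sample(nrow(.fx_diseases), 1L)
    d2 <- sample(setdiff(seq_len(nrow(.fx_diseases)), di), 1L)
    adr_i <- sample(nrow(.fx_adr), 1L)
    draw <- list(
      allele_canonical = names(.fx_alleles)[ai],
      allele_surface = sample(.fx_alleles[[ai]], 1L),
      disease_surface = .fx_diseases$surface[di],
      disease_mesh = .fx_diseases$mesh_id[di],
      disease2_surface = .fx_diseases$surface[d2],
      disease2_mesh = .fx_diseases$mesh_id[d2],
      pop = .fx_pops$surface[sample(nrow(.fx_pops), 1L)],
      rsid = if (cls %in% c("positive", "adr") &&
                 stats::runif(1) < 0.5) sample(.fx_rsids, 1L) else
        NA_character_,
      drug = NA_character_, exposure = FALSE)
    if (cls == "adr") {
      draw$drug <- .fx_adr$drug[adr_i]
      draw$disease_surface <- .fx_adr$surface[adr_i]
      draw$disease_mesh <- .fx_adr$mesh_id[adr_i]
      draw$exposure <- .fx_adr$exposure[adr_i]
    }
    tpl <- .fx_template(cls, draw)
    filler <- sprintf("A total of %d patients and %d controls were enrolled.",
                      sample(50:500, 1L), sample(50:500, 1L))
    abstract <- paste(filler, tpl$text)
    title <- sprintf("Immunogenetic profile of %s.", tpl$mentions$surface[2])
    year <- sample(1975:2021, 1L)
    articles[[i]] <- list(
      pmid = pmid, title = title, abstract = abstract,
      year = year, journal = sample(.fx_journals, 1L),
      types = if (stats::runif(1) < 0.2)
        c("Journal Article", "Review") else "Journal Article")

    truth_abs[[i]] <- data.frame(pmid = pmid, class = cls,
                                 categories = tpl$categories,
                                 stringsAsFactors = FALSE)
    truth_sent[[i]] <- data.frame(pmid = pmid, sentence_index = 1L,
                                  stage1 = tpl$stage1,
                                  final_label = tpl$final,
                                  stringsAsFactors = FALSE)
    truth_men[[i]] <- cbind(pmid = pmid, sentence_index = 1L,
                            tpl$mentions, stringsAsFactors = FALSE)
    if (!is.na(draw$rsid)) {
      truth_snp[[length(truth_snp) + 1L]] <- data.frame(
        pmid = pmid, sentence_index = 1L, rsid = draw$rsid,
        stringsAsFactors = FALSE)
    }
    # every template class except transplant and insulin plants a population
    if (!cls %in% c("transplant", "insulin")) {
      truth_pop[[length(truth_pop) + 1L]] <- data.frame(
        pmid = pmid, surface = tolower(draw$pop),
        bin = .fx_pops$bin[.fx_pops$surface == draw$pop],
        normalized = .fx_pops$normalized[.fx_pops$surface == draw$pop],
        stringsAsFactors = FALSE)
    }
  }

  # incomplete records: title but no abstract
  for (j in seq_len(spec$n_incomplete)) {
    articles[[n + j]] <- list(
      pmid = sprintf("%d", 1100000L + j),
      title = "An incomplete record without abstract text.",
      abstract = NA_character_, year = 2000L,
      journal = .fx_journals[1], types = "Journal Article")
  }

  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (a in articles) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", a$pmid)
    article <- xml2::xml_add_child(cit, "Article")
    journal <- xml2::xml_add_child(article, "Journal")
    issue <- xml2::xml_add_child(journal, "JournalIssue")
    pd <- xml2::xml_add_child(issue, "PubDate")
    xml2::xml_add_child(pd, "Year", as.character(a$year))
    xml2::xml_add_child(journal, "Title", a$journal)
    xml2::xml_add_child(article, "ArticleTitle", a$title)
    if (!is.na(a$abstract)) {
      ab <- xml2::xml_add_child(article, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", a$abstract)
    }
    al <- xml2::xml_add_child(article, "AuthorList")
    au <- xml2::xml_add_child(al, "Author")
    xml2::xml_add_child(au, "LastName", "Doe")
    xml2::xml_add_child(au, "ForeName", "J")
    ptl <- xml2::xml_add_child(article, "PublicationTypeList")
    for (t in a$types) xml2::xml_add_child(ptl, "PublicationType", t)
  }
  xml_path <- file.path(dir, "corpus.xml")
  xml2::write_xml(doc, xml_path)

  bind <- function(lst, empty) {
    if (length(lst)) do.call(rbind, lst) else empty
  }
  truth <- list(
    abstracts = bind(truth_abs, data.frame(pmid = character(),
                                           class = character(),
                                           categories = character())),
    sentences = bind(truth_sent, data.frame(pmid = character(),
                                            sentence_index = integer(),
                                            stage1 = character(),
                                            final_label = character())),
    mentions = bind(truth_men, data.frame(pmid = character(),
                                          sentence_index = integer(),
                                          kind = character(),
                                          surface = character(),
                                          canonical = character())),
    snps = bind(truth_snp, data.frame(pmid = character(),
                                      sentence_index = integer(),
                                      rsid = character())),
    populations = bind(truth_pop, data.frame(pmid = character(),
                                             surface = character(),
                                             bin = character(),
                                             normalized = character())))
  truth_paths <- character(0)
  for (nm in names(truth)) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    .write_tsv(truth[[nm]], p)
    truth_paths[nm] <- p
  }
  list(xml = xml_path, truth = truth, paths = truth_paths)
}
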