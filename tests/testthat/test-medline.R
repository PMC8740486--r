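# MEDLINE parsing, subheading stripping, sentence splitting and the two
# search variants.

simple_record <- function(pmid = "123", title = "A title.",
                          abstract = "HLA-B27 is a risk factor.",
                          with_abstract = TRUE) {
  paste0(
    "<PubmedArticle><MedlineCitation><PMID>", pmid, "</PMID>",
    "<Article><Journal><JournalIssue><PubDate><Year>1999</Year>",
    "</PubDate></JournalIssue><Title>J Immunol</Title></Journal>",
    "<ArticleTitle>", title, "</ArticleTitle>",
    if (with_abstract)
      paste0("<Abstract><AbstractText>", abstract,
             "</AbstractText></Abstract>") else "",
    "<AuthorList><Author><LastName>Doe</LastName>",
    "<ForeName>J</ForeName></Author></AuthorList>",
    "<PublicationTypeList><PublicationType>Journal Article",
    "</PublicationType></PublicationTypeList>",
    "</Article></MedlineCitation></PubmedArticle>")
}

wrap_set <- function(...) {
  paste0("<PubmedArticleSet>", paste(c(...), collapse = ""),
         "</PubmedArticleSet>")
}

test_that("subheading labels are stripped only at label positions", {
  expect_equal(strip_subheadings("BACKGROUND: HLA-B27 is a risk factor."),
               "HLA-B27 is a risk factor.")
  expect_equal(strip_subheadings("HLA-B27 is a risk factor."),
               "HLA-B27 is a risk factor.")
  expect_equal(strip_subheadings("RESULTS: X. CONCLUSION: Y."), "X. Y.")
  # the common noun survives mid-sentence
  expect_equal(strip_subheadings("The results: varied widely."),
               "The results: varied widely.")
  expect_equal(strip_subheadings("We discuss the results of typing."),
               "We discuss the results of typing.")
})

test_that("complete records parse; incomplete records are skipped and logged", {
  recs <- parse_medline(wrap_set(simple_record()))
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$pmid, "123")
  expect_equal(recs$abstract, "HLA-B27 is a risk factor.")
  expect_equal(recs$pub_date, "1999-01-01")
  expect_equal(nrow(attr(recs, "skipped")), 0L)

  recs2 <- parse_medline(wrap_set(simple_record(with_abstract = FALSE)))
  expect_equal(nrow(recs2), 0L)
  expect_equal(nrow(attr(recs2, "skipped")), 1L)
  expect_match(attr(recs2, "skipped")$missing, "abstract")
})

test_that("a 10-record corpus with 3 incomplete yields 7 records", {
  xml <- wrap_set(vapply(1:10, function(i) {
    simple_record(pmid = as.character(i), with_abstract = i > 3)
  }, character(1)))
  recs <- parse_medline(xml)
  # independent count: walk the XML and count records with abstract text
  doc <- xml2::read_xml(xml)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  n_complete <- sum(vapply(arts, function(a) {
    length(xml2::xml_find_all(a, ".//AbstractText")) > 0L
  }, logical(1)))
  expect_equal(nrow(recs), n_complete)
  expect_equal(nrow(recs), 7L)
  expect_equal(nrow(attr(recs, "skipped")), 3L)
})

test_that("parsing is deterministic and errors on malformed XML", {
  xml <- wrap_set(simple_record())
  expect_identical(parse_medline(xml), parse_medline(xml))
  expect_error(parse_medline("<PubmedArticleSet><unclosed>"),
               "malformed")
})

test_that("structured AbstractText labels are recombined then stripped", {
  xml <- wrap_set(paste0(
    "<PubmedArticle><MedlineCitation><PMID>9</PMID>",
    "<Article><Journal><JournalIssue><PubDate><Year>2005</Year></PubDate>",
    "</JournalIssue><Title>J</Title></Journal>",
    "<ArticleTitle>T.</ArticleTitle><Abstract>",
    "<AbstractText Label=\"BACKGROUND\">HLA matters.</AbstractText>",
    "<AbstractText Label=\"RESULTS\">It was associated.</AbstractText>",
    "</Abstract><PublicationTypeList><PublicationType>Journal Article",
    "</PublicationType></PublicationTypeList>",
    "</Article></MedlineCitation></PubmedArticle>"))
  recs <- parse_medline(xml)
  expect_equal(recs$abstract, "HLA matters. It was associated.")
})

test_that("sentence offsets slice the abstract exactly", {
  txt <- "HLA-B*57:01 was tested. It was absent."
  s <- sentence_split(txt, pmid = "1")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text, c("HLA-B*57:01 was tested.", "It was absent."))
  for (i in seq_len(nrow(s))) {
    expect_identical(substr(txt, s$start[i] + 1L, s$end[i]), s$text[i])
  }
  expect_equal(s$index, 0:1)
})

test_that("abbreviation periods do not split sentences", {
  txt <- "Smith et al. reported Chlamydia spp. in 1999. A second study followed."
  s <- sentence_split(txt)
  expect_equal(nrow(s), 2L)
  expect_match(s$text[1], "^Smith et al\\. reported")
  expect_equal(s$text[2], "A second study followed.")
})

test_that("empty abstracts yield no sentences", {
  expect_equal(nrow(sentence_split("")), 0L)
  expect_equal(nrow(sentence_split(NA_character_)), 0L)
})

test_that("search variants keep and strip special characters respectively", {
  v <- preprocess_variants("Graves' disease")
  expect_equal(v$a, "graves' disease")
  expect_equal(v$b, "graves disease")
  v2 <- preprocess_variants("Stevens-Johnson syndrome")
  expect_equal(v2$b, "stevens johnson syndrome")
  v3 <- preprocess_variants("abc")
  expect_equal(v3$a, "abc")
  expect_equal(v3$b, "abc")
})

test_that("variant-B position map is total, unique and order-preserving", {
  texts <- c("Graves' disease (autoimmune)", "B(*)1301 - a risk allele",
             "HLA-B*57:01: carriers", "  spaced   out  text ")
  for (txt in texts) {
    v <- preprocess_variants(txt)
    expect_equal(length(v$map_b), nchar(v$b))
    expect_false(anyDuplicated(v$map_b) > 0)
    expect_true(all(diff(v$map_b) > 0))
    expect_true(all(v$map_b >= 0 & v$map_b < nchar(txt)))
  }
})

test_that("sentence round trip holds across a generated corpus", {
  fx <- generate_corpus(fixture_spec(seed = 11))
  recs <- parse_medline(fx$xml)
  sents <- corpus_sentences(recs)
  for (i in seq_len(nrow(sents))) {
    ab <- recs$abstract[recs$pmid == sents$pmid[i]]
    expect_identical(substr(ab, sents$start[i] + 1L, sents$end[i]),
                     sents$text[i])
  }
  # ordered and non-overlapping within each record
  for (pm in unique(sents$pmid)) {
    s <- sents[sents$pmid == pm, ]
    expect_true(all(diff(s$start) > 0))
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
})
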