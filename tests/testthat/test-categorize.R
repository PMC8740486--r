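# Study-category rules and the anchored biomarker query.

mk_mentions <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(kind = r[[1]], surface = r[[2]], canonical = r[[3]],
               sentence_index = as.integer(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}
mk_sentences <- function(texts) {
  data.frame(pmid = "1", index = seq_along(texts) - 1L, text = texts,
             stringsAsFactors = FALSE)
}

test_that("tree-number branches drive the category assignment", {
  # E04 procedure keyword -> Transplantation
  m <- mk_mentions(list("disease", "bone marrow transplantation",
                        "D016026", 0),
                   list("allele", "B*1301", "HLA-B*13:01", 0))
  s <- mk_sentences("B*1301 matching improved bone marrow transplantation.")
  expect_equal(categorize_abstract(m, s, fx_lex$disease), "Transplantation")

  # C20.452 (GVHD) -> Transplantation, not Diseases
  m2 <- mk_mentions(list("disease", "graft versus host disease",
                         "D006086", 0))
  expect_equal(categorize_abstract(m2, mk_sentences("x"), fx_lex$disease),
               "Transplantation")

  # C23 -> SignsSymptoms
  m3 <- mk_mentions(list("disease", "proteinuria", "D011507", 0))
  expect_equal(categorize_abstract(m3, mk_sentences("x"), fx_lex$disease),
               "SignsSymptoms")

  # plain C branch -> Diseases
  m4 <- mk_mentions(list("disease", "melanoma", "D008545", 0))
  expect_equal(categorize_abstract(m4, mk_sentences("x"), fx_lex$disease),
               "Diseases")
})

test_that("the three-condition ADR rule needs drug+allele+disease together", {
  s <- mk_sentences(paste("Carbamazepine-induced Stevens-Johnson syndrome",
                          "was associated with HLA-B*15:02."))
  m <- mk_mentions(list("disease", "Stevens-Johnson syndrome", "D013262", 0),
                   list("allele", "HLA-B*15:02", "HLA-B*15:02", 0),
                   list("drug", "Carbamazepine", "carbamazepine", 0))
  cats <- categorize_abstract(m, s, fx_lex$disease)
  expect_true("TherapeuticsADR" %in% cats)
  expect_true("Diseases" %in% cats)  # C17 branch hit

  # disease keyword naming "-induced" also satisfies the rule
  s2 <- mk_sentences(paste("Allopurinol exposure was associated with",
                           "drug-induced liver injury in B*5801 carriers."))
  m2 <- mk_mentions(list("disease", "drug-induced liver injury",
                         "D056486", 0),
                    list("allele", "B*5801", "HLA-B*58:01", 0),
                    list("drug", "Allopurinol", "allopurinol", 0))
  expect_true("TherapeuticsADR" %in%
                categorize_abstract(m2, s2, fx_lex$disease))

  # without a drug in the sentence there is no ADR category
  m3 <- m[m$kind != "drug", ]
  expect_false("TherapeuticsADR" %in%
                 categorize_abstract(m3, s, fx_lex$disease))

  # drug present but in a different sentence: still no ADR
  m4 <- m
  m4$sentence_index[m4$kind == "drug"] <- 1L
  s4 <- mk_sentences(c(s$text, "Carbamazepine was prescribed."))
  expect_false("TherapeuticsADR" %in%
                 categorize_abstract(m4, s4, fx_lex$disease))
})

test_that("abstracts may carry several categories; unrooted hits are ignored", {
  m <- mk_mentions(list("disease", "proteinuria", "D011507", 0),
                   list("disease", "melanoma", "D008545", 1))
  s <- mk_sentences(c("a", "b"))
  expect_equal(categorize_abstract(m, s, fx_lex$disease),
               c("Diseases", "SignsSymptoms"))
  m_unrooted <- mk_mentions(list("disease", "mystery", "D999999", 0))
  expect_equal(suppressMessages(
    categorize_abstract(m_unrooted, s, fx_lex$disease)), character(0))
})

test_that("biomarker query ranks bigrams ending in the anchor", {
  sents <- c(rep("HLA-B*27 is a genetic marker for spondylitis.", 3),
             "It is a risk marker in this cohort.",
             "HLA-B*57:01 is a predictive marker for abacavir hypersensitivity.")
  q <- biomarker_query(sents)
  expect_equal(q$ngram[1], "genetic marker")
  expect_equal(q$count[1], 3L)
  expect_true("risk marker" %in% q$ngram)
  expect_true("predictive marker" %in% q$ngram)
  expect_equal(nrow(biomarker_query("No anchor word here.")), 0L)
})
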