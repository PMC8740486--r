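# Co-occurrence screening and dictionary matching against brute-force
# oracles.

test_that("longest keyword wins over nested dictionary hits", {
  m <- match_diseases("Children with type 1 diabetes mellitus were typed.",
                      fx_lex$disease)
  expect_equal(nrow(m), 1L)
  expect_equal(m$surface, "type 1 diabetes mellitus")
  expect_equal(m$canonical, "D003922")
  # oracle agreement on the same sentence
  tab <- fx_lex$disease$entries$surface
  o <- oracle_match("Children with type 1 diabetes mellitus were typed.",
                    tab, "[A-Za-z0-9]")
  expect_equal(m$start, o$start)
  expect_equal(m$end, o$end)
})

test_that("special-character variants match through variant B", {
  m <- match_diseases("A case of Stevens Johnson syndrome was reported.",
                      fx_lex$disease)
  expect_equal(m$surface, "Stevens Johnson syndrome")
  expect_equal(m$canonical, "D013262")
  expect_equal(m$variant, "B")
  expect_equal(nrow(match_diseases("Nothing to see here.", fx_lex$disease)),
               0L)
})

test_that("allele matching respects the extended boundary class", {
  m <- match_alleles("Carriers of B*1301 were at increased risk.",
                     fx_lex$allele)
  expect_equal(m$surface, "B*1301")
  expect_equal(m$canonical, "HLA-B*13:01")
  expect_equal(nrow(match_alleles("The probe 4B1301X was unrelated.",
                                  fx_lex$allele)), 0L)
  # mention surface slices the original sentence
  s <- "Carriers of B*1301 were at increased risk."
  expect_identical(substr(s, m$start + 1L, m$end), m$surface)
})

test_that("abstracts are screened on joint allele + disease presence", {
  keep <- list(title = "HLA-B*57:01 screening",
               abstract = "We studied ankylosing spondylitis cases.")
  expect_true(screen_abstract(keep, fx_lex$allele, fx_lex$disease))
  drop1 <- list(title = "A cohort study",
                abstract = "Two hundred patients were enrolled.")
  expect_false(screen_abstract(drop1, fx_lex$allele, fx_lex$disease))
  allele_only <- list(title = "HLA-B*57:01 typing",
                      abstract = "Frequencies were tabulated.")
  expect_false(screen_abstract(allele_only, fx_lex$allele, fx_lex$disease))
})

test_that("only sentences co-mentioning allele and disease are retained", {
  texts <- c("HLA-DRB1*15:01 was protective for multiple sclerosis.",
             "The cohort comprised 200 patients.",
             "B*1301 carriers developed psoriasis.",
             "Melanoma incidence rose.",
             "HLA-B*57:01 was typed.",
             "No entities at all here.")
  sentences <- data.frame(pmid = "1", index = seq_along(texts) - 1L,
                          text = texts, start = 0L, end = nchar(texts))
  mentions <- do.call(rbind, lapply(seq_along(texts), function(i) {
    m <- rbind(match_alleles(texts[i], fx_lex$allele),
               match_diseases(texts[i], fx_lex$disease))
    if (nrow(m)) cbind(pmid = "1", sentence_index = i - 1L, m)
  }))
  kept <- filter_cooccurrence_sentences(sentences, mentions)
  expect_equal(kept$index, c(0L, 2L))
})

test_that("failing the screen implies no retained sentences", {
  rec <- list(title = "HLA-B*57:01 typing",
              abstract = "HLA-B*57:01 frequencies were tabulated. Controls were typed.")
  expect_false(screen_abstract(rec, fx_lex$allele, fx_lex$disease))
  sents <- sentence_split(rec$abstract, pmid = "x")
  mentions <- do.call(rbind, lapply(seq_len(nrow(sents)), function(i) {
    m <- rbind(match_alleles(sents$text[i], fx_lex$allele),
               match_diseases(sents$text[i], fx_lex$disease))
    if (nrow(m)) cbind(pmid = "x", sentence_index = sents$index[i], m)
  }))
  if (is.null(mentions)) mentions <- data.frame(pmid = character(),
                                                sentence_index = integer(),
                                                kind = character())
  expect_equal(nrow(filter_cooccurrence_sentences(sents, mentions)), 0L)
})

test_that("adding a lexicon keyword never decreases retained sentences", {
  texts <- c("HLA-B*57:01 carriers had eruptions.",
             "B*1301 was linked to psoriasis.",
             "Patients with melanoma were excluded.")
  sentences <- data.frame(pmid = "1", index = 0:2, text = texts,
                          start = 0L, end = nchar(texts))
  count_kept <- function(dlex) {
    mentions <- do.call(rbind, lapply(1:3, function(i) {
      m <- rbind(match_alleles(texts[i], fx_lex$allele),
                 match_diseases(texts[i], dlex))
      if (nrow(m)) cbind(pmid = "1", sentence_index = i - 1L, m)
    }))
    nrow(filter_cooccurrence_sentences(sentences, mentions))
  }
  base <- count_kept(fx_lex$disease)
  # widen the dictionary with a keyword hitting sentence 1
  wider <- fx_lex$disease
  wider$entries <- rbind(wider$entries,
                         data.frame(surface = "eruptions",
                                    mesh_id = "D005076",
                                    descriptor_type = "ET",
                                    unrooted = TRUE))
  wider$cache <- new.env(parent = emptyenv())
  expect_gte(count_kept(wider), base)
  expect_equal(count_kept(wider), base + 1L)
})

test_that("matchers agree with the brute-force oracle on a small corpus", {
  texts <- random_fixture_sentences(20, seed = 99)
  dis_surf <- fx_lex$disease$entries$surface
  al_tab <- ls(fx_lex$allele$surfaces)
  for (txt in texts) {
    md <- match_diseases(txt, fx_lex$disease)
    od <- oracle_match(txt, dis_surf, "[A-Za-z0-9]")
    expect_equal(md$start, od$start, info = txt)
    expect_equal(md$end, od$end, info = txt)
    ma <- match_alleles(txt, fx_lex$allele)
    oa <- oracle_match(txt, al_tab, "[A-Za-z0-9*:]")
    expect_equal(ma$start, oa$start, info = txt)
    expect_equal(ma$end, oa$end, info = txt)
  }
})
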