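# Coding vectors, stage-1 mapping, masking, root verbs, final labels and
# the n-gram harvester.

lab <- load_label_lexicon()
vp <- load_verb_polarity()

test_that("label detection sets coding-vector bits from token presence", {
  v <- detect_labels("HLA-B*57:01 was significantly associated with it.",
                     lab)
  expect_true(v$has_pos)
  expect_false(v$has_neg)
  expect_false(v$has_negation)
  v0 <- detect_labels("The cohort comprised adults.", lab)
  expect_equal(unlist(v0[c("has_pos", "has_neg", "has_negation")]),
               c(has_pos = FALSE, has_neg = FALSE, has_negation = FALSE))
  vn <- detect_labels("No association was found.", lab)
  expect_true(vn$has_negation)
})

test_that("longer labels shadow nested shorter ones of opposite polarity", {
  v <- detect_labels("It was negatively associated with the disease.", lab)
  expect_true(v$has_neg)
  expect_false(v$has_pos)  # "associated" is consumed by the bigram
})

test_that("carrier-status guard blocks allele-adjacent polarity tokens", {
  am <- data.frame(kind = "allele", start = 0L, end = 11L)
  v <- detect_labels("HLA-B*57:01 negative patients were excluded.", lab,
                     allele_mentions = am)
  expect_false(v$has_neg)
  # beyond the guard window the token counts again
  v2 <- detect_labels("HLA-B*57:01 carriers were often negative.", lab,
                      allele_mentions = am)
  expect_true(v2$has_neg)
  # without an allele nearby the token is an association label
  v3 <- detect_labels("The overall association was negative.", lab)
  expect_true(v3$has_neg)
})

test_that("all 8 coding vectors map to the expected stage-1 labels", {
  grid <- expand.grid(p = c(FALSE, TRUE), n = c(FALSE, TRUE),
                      g = c(FALSE, TRUE))
  got <- code_to_stage1_label(grid$p, grid$n, grid$g)
  want <- ifelse(grid$p & grid$n, "complex",
          ifelse(grid$p & grid$g, "ambiguous",
          ifelse(grid$n & grid$g, "ambiguous",
          ifelse(grid$p, "positive",
          ifelse(grid$n, "negative",
          ifelse(grid$g, "negation", "others"))))))
  expect_identical(got, want)
  expect_length(unique(got), 6L)
})

test_that("entity masking replaces mentions and preserves other text", {
  s <- "Multiple sclerosis is linked to HLA-DRB1*15:01"
  m <- rbind(match_diseases(s, fx_lex$disease),
             match_alleles(s, fx_lex$allele))
  expect_equal(mask_entities(s, m), "@DISEASE is linked to @GENE")
  expect_equal(mask_entities("Nothing here.",
                             m[0, , drop = FALSE]), "Nothing here.")
  s2 <- "B*1301 and B*5701 predispose to psoriasis"
  m2 <- rbind(match_alleles(s2, fx_lex$allele),
              match_diseases(s2, fx_lex$disease))
  masked2 <- mask_entities(s2, m2)
  expect_equal(lengths(regmatches(masked2, gregexpr("@GENE", masked2))), 2L)
  expect_equal(lengths(regmatches(masked2, gregexpr("@DISEASE", masked2))),
               1L)
  # non-entity token multiset is preserved
  left <- tokenize_text(masked2)$norm
  left <- left[!left %in% c("@gene", "@disease")]
  orig <- tokenize_text(s2)$norm
  orig <- orig[!orig %in% c("b*1301", "b*5701", "psoriasis")]
  expect_identical(sort(left), sort(orig))
  bad <- data.frame(kind = c("allele", "disease"),
                    start = c(0L, 3L), end = c(6L, 10L))
  expect_error(mask_entities(s2, bad), "overlapping")
})

test_that("root verbs are found, lemmatized and classified", {
  r1 <- root_verb(
    "To investigate the association of @GENE with @DISEASE in children.",
    vp)
  expect_equal(r1, list(verb = "investigate", class = "investigatory"))
  r2 <- root_verb("@GENE is associated with @DISEASE", vp)
  expect_equal(r2, list(verb = "associate", class = "positive"))
  r3 <- root_verb("@GENE protected against @DISEASE", vp)
  expect_equal(r3, list(verb = "protect", class = "negative"))
  expect_equal(root_verb("", vp), list(verb = "", class = "unknown"))
  r4 <- root_verb("@GENE was genotyped in patients with @DISEASE.", vp)
  expect_equal(r4$class, "unknown")
  # injected parser takes precedence
  r5 <- root_verb("@GENE whatever @DISEASE", vp,
                  parser = function(text) list(verb = "protects"))
  expect_equal(r5, list(verb = "protect", class = "negative"))
})

test_that("the final-label decision table is total over the 24-cell grid", {
  stages <- c("positive", "negative", "negation", "complex", "ambiguous",
              "others")
  verbs <- c("positive", "negative", "investigatory", "unknown")
  grid <- expand.grid(s = stages, v = verbs, stringsAsFactors = FALSE)
  got <- annotate_sentence(grid$s, grid$v)
  expect_length(got, 24L)
  expect_true(all(got %in% c("Positive", "Negative", "Complex", "Ambiguous",
                             "Investigatory", "Others")))
  expect_equal(annotate_sentence("positive", "positive"), "Positive")
  expect_equal(annotate_sentence("negative", "negative"), "Negative")
  expect_equal(annotate_sentence("complex", "unknown"), "Complex")
  expect_equal(annotate_sentence("ambiguous", "positive"), "Ambiguous")
  expect_equal(annotate_sentence("negation", "negative"), "Ambiguous")
  expect_equal(annotate_sentence("others", "investigatory"),
               "Investigatory")
  # polarity disagreement falls through to Others
  expect_equal(annotate_sentence("positive", "negative"), "Others")
  expect_equal(annotate_sentence("others", "unknown"), "Others")
})

test_that("n-gram harvesting counts POS-filtered candidates above cutoff", {
  corpus <- c(rep("The allele was strongly associated with disease.", 6),
              rep("Cases were reported in the registry.", 3),
              "Controls were unrelated individuals.")
  cand <- build_ngram_candidates(corpus, freq_cutoff = 5)
  expect_true("associated" %in% cand$ngram[cand$n == 1])
  expect_equal(cand$count[cand$ngram == "associated"], 6L)
  expect_true("strongly associated" %in% cand$ngram[cand$n == 2])
  expect_false("reported" %in% cand$ngram)  # below cutoff
  # cutoff 1 on a one-sentence corpus keeps every eligible n-gram
  all1 <- build_ngram_candidates("It was strongly associated.",
                                 freq_cutoff = 1)
  expect_true(all(c("strongly", "associated",
                    "strongly associated") %in% all1$ngram))
  # counts are sorted descending with lexicographic ties
  expect_true(all(diff(cand$count) <= 0))
  empty <- build_ngram_candidates(character(0))
  expect_equal(nrow(empty), 0L)
})
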