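# Disease, allele and drug dictionaries and their normalization maps.

test_that("DEV keyword rows are excluded; unknown types warn", {
  lex <- fx_lex$disease
  expect_false(any(lex$entries$descriptor_type == "DEV"))
  expect_false("abdominal inj" %in% lex$entries$surface)
  expect_true("abdominal injuries" %in% lex$entries$surface)

  rows <- data.frame(keyword = c("thing", "odd"),
                     descriptor_type = c("MH", "XX"),
                     mesh_id = c("D000001", "D000002"))
  tree <- data.frame(mesh_id = "D000001", label = "Thing",
                     tree_number = "C01")
  expect_warning(lex2 <- build_disease_lexicon(rows, tree), "XX")
  expect_false("odd" %in% lex2$entries$surface)
})

test_that("keyword variants share one MeSH ID and plurals are generated", {
  e <- fx_lex$disease$entries
  t1d <- e[e$surface %in% c("type 1 diabetes", "type 1 diabetes mellitus",
                            "insulin dependent diabetes mellitus"), ]
  expect_equal(unique(t1d$mesh_id), "D003922")
  tumor <- e[e$surface %in% c("tumor", "tumors"), ]
  expect_equal(nrow(tumor), 2L)
  expect_equal(unique(tumor$mesh_id), "D009369")
  expect_true("plural-variant" %in% tumor$descriptor_type)
})

test_that("disease surfaces normalize to the shared malignancy descriptor", {
  expect_equal(normalize_disease(fx_lex$disease, "cancer")$mesh_id, "D009369")
  expect_equal(normalize_disease(fx_lex$disease, "malignancy")$mesh_id,
               "D009369")
  n <- normalize_disease(fx_lex$disease, "melanoma")
  expect_equal(n$mesh_id, "D008545")
  expect_equal(n$level_one, "Neoplasms")
  expect_equal(n$level_zero, "Diseases")
  expect_error(normalize_disease(fx_lex$disease, "notadisease"), "unknown")
})

test_that("tree-number ancestors resolve at level zero and one", {
  h <- fx_lex$disease$hierarchy
  a0 <- mesh_ancestor(h, "C20.452.274", 0L)
  expect_equal(a0$label, "Diseases")
  a1 <- mesh_ancestor(h, "C20.452.274", 1L)
  expect_equal(a1$mesh_id, "D007154")
  expect_equal(a1$label, "Immune System Diseases")
  expect_null(mesh_ancestor(h, "C99.1", 1L))
})

test_that("every tree number resolves to exactly one level-zero root", {
  h <- fx_lex$disease$hierarchy
  for (tn in h$tree$tree_number) {
    a0 <- mesh_ancestor(h, tn, 0L)
    expect_false(is.null(a0))
    expect_length(a0$label, 1L)
  }
})

test_that("allele surface variants cover the printed nomenclature forms", {
  for (s in c("HLA-B*13:01", "HLA-B*1301", "B*1301", "B(*)1301", "B1301")) {
    expect_equal(normalize_allele(fx_lex$allele, s),
                 "HLA-B*13:01", ignore_attr = TRUE)
  }
  # full enumeration for one allele: prefix x star-style x separator
  expected <- c("hla-b*13:01", "hla-b*1301", "hla-b(*)13:01",
                "hla-b(*)1301", "hla-b13:01", "hla-b1301",
                "b*13:01", "b*1301", "b(*)13:01", "b(*)1301",
                "b13:01", "b1301")
  for (s in expected) {
    expect_true("HLA-B*13:01" %in% normalize_allele(fx_lex$allele, s))
  }
})

test_that("old nomenclature maps to current names; retired names drop out", {
  expect_equal(normalize_allele(fx_lex$allele, "DR15"),
               "HLA-DRB1*15:01", ignore_attr = TRUE)
  expect_true("Cw*0602" %in% fx_lex$allele$retired)
  expect_error(normalize_allele(fx_lex$allele, "cw*0602"), "unknown")
})

test_that("broad-antigen surfaces return all candidates flagged ambiguous", {
  hit <- normalize_allele(fx_lex$allele, "B22")
  expect_equal(sort(as.character(hit)),
               c("HLA-B*54:01", "HLA-B*55:01", "HLA-B*56:01"))
  expect_true(attr(hit, "ambiguous"))
  one <- normalize_allele(fx_lex$allele, "b*5701")
  expect_false(attr(one, "ambiguous"))
})

test_that("allele normalization is idempotent and surfaces round-trip", {
  surfaces <- ls(fx_lex$allele$surfaces)
  for (s in surfaces) {
    first <- normalize_allele(fx_lex$allele, s)
    for (canon in first) {
      p <- parse_allele_name(canon)
      if (is.null(p)) next  # generic / haplotype names
      again <- normalize_allele(fx_lex$allele, canon)
      expect_true(canon %in% again)
    }
  }
})

test_that("two-digit collapsing keeps locus plus first field", {
  expect_equal(collapse_two_digit("HLA-B*13:01"), "HLA-B*13")
  expect_equal(collapse_two_digit("HLA-DRB1*15"), "HLA-DRB1*15")
  expect_equal(collapse_two_digit("HLA-B*38:02:01"), "HLA-B*38")
  # idempotence over fixture canonicals
  canons <- fx_lex$allele$entries$canonical[
    fx_lex$allele$entries$category %in% c("current", "old-mapped")]
  expect_identical(collapse_two_digit(collapse_two_digit(canons)),
                   collapse_two_digit(canons))
  expect_error(collapse_two_digit("HLA class I"), "not collapsible")
})

test_that("drug lexicon dedupes case-folded across sources", {
  drugs <- build_drug_lexicon(
    data.frame(name = c("Carbamazepine", "abacavir", "dapsone",
                        "allopurinol", "insulin")),
    list(AFND = c("methimazole", "carbimazole"),
         PharmGKB = c("carbamazepine", "phenytoin")))
  expect_equal(nrow(drugs), 8L)  # 5 + 2 + 2 with 1 overlap
  cz <- drugs[drugs$name == "carbamazepine", ]
  expect_equal(cz$sources, "PharmGKB;SIDER")
  expect_warning(empty <- build_drug_lexicon(NULL, list()), "empty")
  expect_equal(nrow(empty), 0L)
})
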