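Package: hlatext
Title: Dictionary-Based Mining of HLA Allele-Disease Associations from
    Biomedical Abstracts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A text-mining toolkit for curating associations between HLA
    (human leukocyte antigen) alleles and diseases from MEDLINE/PubMed
    abstracts.  Parses PubMed XML into clean abstract records, compiles
    keyword dictionaries for diseases (MeSH descriptors with tree-number
    hierarchy), HLA alleles (with exhaustive nomenclature surface variants
    and old-to-new name mapping) and drugs, screens abstracts for
    allele-disease co-mentions, tags SNP rsIDs, drugs and populations, and
    assigns each co-occurrence sentence a polarity label (positive, negative,
    complex, ambiguous, investigatory, others) via a hybrid n-gram
    label-lexicon plus root-verb scheme with negation handling and a
    carrier-status guard.  Abstracts are grouped into disease,
    transplantation, signs-and-symptoms and therapeutics/adverse-drug-reaction
    categories, and all tables export deterministically.  A seeded synthetic
    corpus generator with planted ground truth makes every stage testable
    offline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
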