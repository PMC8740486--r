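---
title: "Mining HLA allele-disease associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining HLA allele-disease associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlatext)
```

## Overview

`hlatext` extracts structured allele-disease association records from
biomedical abstracts with a fully dictionary-based pipeline: no trained
models are required at any stage, every decision is rule-driven, and every
rule is testable against planted ground truth.  This vignette explains the
method, the tunable parameters, what the synthetic-corpus generator does
and does not emulate, and the design decisions taken where the problem was
genuinely open.

## Parsing and sentence handling

PubMed XML records are kept only when they carry a PMID, title, abstract,
publication date, journal and at least one publication type; authors are
optional (`require_authors = TRUE` tightens this).  Requiring the full
field set keeps downstream tables join-safe; the skip log preserves an
audit trail of what was dropped and why.

Structured-abstract section labels (background, introduction, objective,
method, experimental design, result, discussion, importance, setting,
design, study objective, patients, participants, conclusion) are removed
only when they appear as labels — at the start of the text, after a
newline, or after sentence-final punctuation, and followed by a colon.
Matching label positions rather than words keeps the common nouns
"results" or "design" intact mid-sentence.  Both inline labels
(`RESULTS: ...`) and structured `AbstractText@Label` attributes are
handled: labelled sections are recombined as `LABEL: text` and then
cleaned through the same path, so the two XML dialects behave identically.

The sentence splitter is rule-based: a sentence ends at `.`, `!` or `?`
followed by whitespace and a capital or digit, unless the preceding token
is a known abbreviation (`et al.`, `spp.`, `Fig.` ...) or a single
initial.  The splitter is deliberately pluggable (any function returning
offset-tracked spans can replace it); the default avoids model downloads
and guarantees the round-trip invariant that each sentence's 0-based
half-open offsets slice the cleaned abstract to exactly its text.  All
offsets in the package are 0-based half-open.

Each sentence is searched in two lower-cased variants.  Variant A keeps
special characters, so `Graves' disease` matches as written.  Variant B
deletes `' ( ) * :`, turns dashes into spaces and collapses whitespace
runs, so `Stevens-Johnson syndrome` also matches `Stevens Johnson
syndrome`.  A position map from every variant-B character back to its
original offset makes all reported mentions refer to the original text.
Both directions matter: the keyword may carry the special character and
the sentence not, or vice versa, so variant B is scanned for every
keyword, not only for keywords containing specials.

## Dictionaries

**Diseases.**  MeSH keyword rows of term types ET, MH, PEP, DSV and PM are
retained; DEV rows are excluded because those strings are truncated forms
("abdominal inj") that would poison boundary-based matching.  Every
keyword additionally emits a plural variant (s/es rules plus an
irregular-noun table) and a lemmatized variant (rule-based singularizer;
the lemmatizer is an injectable function), all pointing at the same MeSH
descriptor.  Descriptors carry tree numbers; level zero of a tree number
is its branch root (`C` = Diseases) and level one its top-level descriptor
(`C20` = Immune System Diseases), which is how disease mentions are rolled
up for summaries.

**Alleles.**  Canonical names are fixed to the current IMGT-style form
`HLA-GENE*F1:F2...`.  Every allele in the list contributes its exact name
and, when it has more than two fields, its two-field truncation; each
generates the full surface-variant set over prefix presence, star style
(`*`, `(*)`, none) and field-separator presence — twelve surfaces for a
two-field allele.  History rows map old names onto current canonicals;
rows whose current name is empty are retired and excluded from matching.
Broad-antigen and haplotype groups ship as editable YAML because no
authoritative machine-readable table exists; their surfaces resolve to all
member canonicals with an explicit ambiguity flag.  A locus-priority
tie-break for digit-collapsed old names turned out to be unnecessary:
every generated surface carries its locus token, so the only ambiguity
sources are the group entries, which are flagged rather than resolved.

**Drugs.**  A SIDER-style name list plus supplemental lists
(allele-frequency and pharmacogenomics resources, local config), deduped
case-folded with provenance retained.

## Matching rules

Dictionary hits use class-specific boundary rules: a surface only matches
when flanked by characters outside `[A-Za-z0-9]` (diseases, drugs) or
`[A-Za-z0-9*:]` (alleles — standard word boundaries fail next to `*`, and
`4B1301X` must not match `B1301`).  Overlapping hits resolve
longest-match-wins with left-most tie-breaking, so `type 1 diabetes
mellitus` yields one mention, not three.  An abstract is kept when title
or text jointly contain at least one allele and one disease surface;
sentence-level co-occurrence of both then gates all semantic analysis.
Title matches count for screening but title text is not a sentence-label
candidate: polarity statements live in abstract bodies.

Drug mentions fully contained in a disease mention span are discarded
(*insulin* inside *insulin dependent diabetes mellitus*).  SNP tagging
follows the literal pattern `rs` + at least two digits, case-insensitive,
with no upper digit bound, normalized to a lower-case `rs` prefix and
deduplicated in first-occurrence order.  Population mentions are searched
over whole abstracts — population names rarely share a sentence with the
allele and disease — through an injected token-classification backend; only
NORP-class entities are kept because GPE tags capture organism scientific
names (Chlamydia, Chlamydomonas) in biomedical text.  The default backend
is a gazetteer over the shipped country/ethnic-group tables, which keeps
the core model-free; those tables are miniature curated stand-ins seeded
from printed examples, not a reconstruction of any published binning.

## Sentence polarity: the hybrid scheme

Stage 1 scans sentence tokens for three curated sets: positive association
labels, negative association labels and negation words (`not`, `none`,
`no`).  Multiword labels match as token sequences and longer labels shadow
nested shorter ones, so `negatively associated` does not also fire
`associated`.  The presence bits form a coding vector mapped totally onto
stage-1 labels:

| positive | negative | negation | stage 1 |
|---|---|---|---|
| 1 | 0 | 0 | positive |
| 0 | 1 | 0 | negative |
| 0 | 0 | 1 | negation |
| 1 | 1 | any | complex |
| 1 | 0 | 1 | ambiguous |
| 0 | 1 | 1 | ambiguous |
| 0 | 0 | 0 | others |

This table is this package's explicit definition: it reproduces the named
outcome classes (positive, negative, negation, complex, ambiguous, others)
and errs conservatively — any co-occurrence of contradictory or negated
signals is pushed toward complex/ambiguous rather than a polarity call,
matching the stringency appropriate for negative labels.  Negation scope
is whole-sentence presence; the exception is the carrier-status guard: the
tokens `negative`/`positive` within `k_guard` (default 2) tokens after an
allele mention describe allele carriage ("HLA-B27 negative" = the allele
is absent), never association polarity, and are ignored.

The second signal is the root verb.  Allele and disease mentions are first
masked to `@GENE` and `@DISEASE` (right-to-left, so offsets stay valid) —
without masking, multiword entities fragment into several parse tokens.
A dependency parser can be injected; the default is a part-of-speech
heuristic that takes the first verb-like token outside a to-infinitival
purpose clause, skipping auxiliaries, and treats a sentence-initial
purpose clause ("To investigate ...") as naming the root.  The lemma is
classified by a curated verb-polarity lexicon
(positive/negative/investigatory); unknown lemmas stay `unknown`.

The final label combines both: polarity agreement gives Positive or
Negative; stage-1 complex is Complex; ambiguous or negation-only is
Ambiguous (negation-only sentences are folded into Ambiguous rather than
surfaced as a seventh class, since only six final classes exist);
an investigatory root verb without polarity agreement gives Investigatory;
everything else — including outright disagreement such as a positive
stage-1 label with a negative verb — is Others, on the principle that
conflicting evidence should never produce a confident polarity.

The shipped label table (`semantic_labels_synthetic.tsv`) is a synthetic
stand-in for a manually curated lexicon: 1107 positive entries built from
association verbs and adverb-verb bigrams and 20 negative entries
(protection/resistance phrases plus `negative`), matching the published
curation's size and split.  It is a constructed artifact, clearly labelled
synthetic; real curation would replace it file-for-file.  The n-gram
harvester (`build_ngram_candidates()`) exists to regenerate such a lexicon
from any corpus: verb/adverb unigrams and adjacent adverb-verb bi/trigrams
above a frequency cutoff (default 10, configurable; a cutoff exists to
suppress hapax noise, and 10 is a round choice at desk scale), ranked for
manual curation.  Its POS guesses are heuristic (suffix rules plus a verb
lexicon) and its default lemmatizer is the identity, so harvested
candidates read exactly as they appear in text.

## Categories

Per abstract: any disease mention whose tree number falls under `C23`
gives Signs&Symptoms; under `C20.452` (graft-versus-host disease) or `E04`
(operative procedures) gives Transplantation; Therapeutics/ADR requires a
single sentence co-mentioning drug, allele and disease *and* one of three
signals (disease in the ADR MeSH branch, default `C25`
chemically-induced disorders; a `reactions`/`-induced` token in the
sentence; `-induced` inside the disease keyword itself); any remaining
C-branch hit gives Diseases.  Category membership is a set — an abstract
can be both Transplantation and Diseases; exclusive counting is a
reporting choice, not a property of the data, so it is left to consumers.

## The synthetic corpus: what it does and does not show

`generate_corpus()` builds abstracts from slot-filled sentence templates —
one filler sentence plus one template sentence per abstract — with planted
alleles (sampled across all nomenclature variants), diseases, drugs,
rsIDs and populations, all inside lexicon coverage by construction, and
writes the intended mentions, stage-1 labels, final labels and categories
as truth tables.  The default class mix (5 positive, 3 negative, 2 each of
negation/investigatory/complex/others, 2 ADR, 2 transplantation, 2
signs-and-symptoms, 1 drug-false-positive abstract) exercises every
decision path; the test suite and acceptance script scale the same
template mix to 200 abstracts, a size chosen so the full pipeline runs in
seconds on one CPU while leaving every code path covered.

Passing with precision and recall 1.0 on this corpus shows that parsing,
normalization, matching, guard logic, labelling and categorization
implement their rules exactly.  It does **not** show robustness to real
abstracts: real language has labels outside any lexicon, entities with
typos, polarity expressed across clauses, and parser-worthy syntax that
the POS heuristic only approximates.  Template generation is deliberately
not a language model — exact ground truth is the point — so corpus-level
recall on MEDLINE cannot be inferred from these tests.

## Numerical and degenerate-input choices

Determinism everywhere: ties in overlap resolution break left-most; ties
in frequency rankings break lexicographically; exports sort by (pmid,
sentence index, span start) and are byte-identical across runs at a fixed
seed.  Degenerate inputs return typed empties rather than errors (empty
abstract → no sentences; empty corpus → header-only exports); the two
hard errors are reserved for upstream bugs (overlapping mention spans in
masking) and unknown lookups (`normalize_allele`/`normalize_disease` on
unknown surfaces).  A failing population NER backend degrades to empty
tags with a warning so the pipeline completes.

## Known limitations

- Dictionary NER cannot find entities absent from the dictionaries;
  recall on real text is bounded by lexicon coverage.
- The default root-verb heuristic is not a parser; garden-path sentences
  and long coordinations can mislabel the root.  Injecting a dependency
  parser is the intended remedy.
- The shipped label lexicon, population tables and allele groups are
  synthetic or miniature stand-ins; production use requires the real
  curated resources in the same file formats.
- Relation aggregation across sentences and learned relation extraction
  are out of scope by design.
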