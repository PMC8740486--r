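# Shared fixtures and independent brute-force oracles.  The oracles do
# their own preprocessing and position-by-position scanning so they verify
# the matchers without reusing the matching code path.

# One lexicon bundle for the whole suite (building it is cheap but not free).
fx_lex <- fixture_lexicons()

# --- brute-force dictionary-match oracle ---------------------------------

# Independent variant-B construction: delete ' ( ) * :, dashes to spaces,
# collapse space runs; returns the string and a 0-based offset map.
oracle_variant_b <- function(text) {
  chars <- strsplit(tolower(text), "")[[1]]
  b <- character(0); map <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c("'", "’", "‘", "(", ")", "*", ":")) next
    if (ch %in% c("-", "–", "—") || ch %in% c(" ", "\t", "\n")) {
      if (length(b) == 0L || b[length(b)] == " ") next
      b <- c(b, " "); map <- c(map, i - 1L)
    } else {
      b <- c(b, ch); map <- c(map, i - 1L)
    }
  }
  while (length(b) && b[length(b)] == " ") {
    b <- b[-length(b)]; map <- map[-length(map)]
  }
  list(text = paste(b, collapse = ""), map = map)
}

# Every boundary-respecting occurrence of every surface, tested at every
# position of both variants via vectorized substring comparison, then
# longest-match-wins / left-most greedy resolution.
oracle_match <- function(text, surfaces, boundary_class,
                         surfaces_b = NULL) {
  if (is.null(surfaces_b)) {
    surfaces_b <- vapply(surfaces, function(s) oracle_variant_b(s)$text,
                         character(1), USE.NAMES = FALSE)
  }
  is_boundary <- function(ch) grepl(boundary_class, ch)
  scan <- function(hay, needle) {
    n <- nchar(hay); len <- nchar(needle)
    if (len > n) return(integer(0))
    starts <- which(substring(hay, 1:(n - len + 1L),
                              len:(n)) == needle)
    ok <- vapply(starts, function(p) {
      before <- if (p > 1L) substr(hay, p - 1L, p - 1L) else ""
      after <- if (p + len <= n) substr(hay, p + len, p + len) else ""
      !(nzchar(before) && is_boundary(before)) &&
        !(nzchar(after) && is_boundary(after))
    }, logical(1))
    starts[ok]
  }
  a <- tolower(text)
  vb <- oracle_variant_b(text)
  spans <- list()
  for (k in seq_along(surfaces)) {
    s <- surfaces[k]
    for (p in scan(a, tolower(s))) {
      spans[[length(spans) + 1L]] <- c(p - 1L, p - 1L + nchar(s))
    }
    sb <- surfaces_b[k]
    if (nzchar(sb)) {
      for (p in scan(vb$text, sb)) {
        spans[[length(spans) + 1L]] <-
          c(vb$map[p], vb$map[p + nchar(sb) - 1L] + 1L)
      }
    }
  }
  if (!length(spans)) {
    return(data.frame(start = integer(), end = integer()))
  }
  sp <- unique(do.call(rbind, spans))
  sp <- sp[order(-(sp[, 2] - sp[, 1]), sp[, 1]), , drop = FALSE]
  keep <- rep(TRUE, nrow(sp))
  for (i in seq_len(nrow(sp))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(sp)) > i &
                 sp[, 1] < sp[i, 2] & sp[, 2] > sp[i, 1])
    keep[j] <- FALSE
  }
  sp <- sp[keep, , drop = FALSE]
  sp <- sp[order(sp[, 1]), , drop = FALSE]
  data.frame(start = sp[, 1], end = sp[, 2])
}

# Brute-force rsID oracle: character scan for rs/RS/Rs/rS followed by a
# maximal digit run of length >= 2.
oracle_snps <- function(text) {
  chars <- strsplit(text, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i < length(chars)) {
    if (tolower(chars[i]) == "r" && tolower(chars[i + 1L]) == "s") {
      j <- i + 2L
      while (j <= length(chars) && grepl("[0-9]", chars[j])) j <- j + 1L
      ndig <- j - (i + 2L)
      if (ndig >= 2L) {
        out <- c(out, paste0("rs", paste(chars[(i + 2L):(j - 1L)],
                                         collapse = "")))
        i <- j
        next
      }
    }
    i <- i + 1L
  }
  unique(out)
}

# Random fixture sentences mixing plain words, planted surfaces, embedded
# (boundary-violating) tokens and rs-like strings.
random_fixture_sentences <- function(n, seed) {
  set.seed(seed)
  words <- c("patients", "with", "the", "cohort", "study", "showed",
             "risk", "allele", "frequency", "analysis", "group", "were")
  planted <- c("B*1301", "HLA-B*13:01", "B(*)1301", "hla-b*5701",
               "melanoma", "type 1 diabetes", "Stevens Johnson syndrome",
               "multiple sclerosis", "psoriasis")
  decoys <- c("4B1301X", "melanomatosis", "rs9", "rs", "XB*1301",
              "B*1301ish")
  rs <- c("rs9277535", "RS12", "rs345", "rs12")
  vapply(seq_len(n), function(i) {
    k <- sample(4:12, 1)
    toks <- sample(c(sample(words, k, replace = TRUE),
                     sample(planted, sample(0:3, 1)),
                     sample(decoys, sample(0:2, 1)),
                     sample(rs, sample(0:2, 1))))
    paste0(paste(toks, collapse = " "), ".")
  }, character(1))
}
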