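# Independent naive reference implementations used as oracles. These
# deliberately share no code with the package: their own tokenizer, full
# rescans instead of inverted indices, and direct formula evaluation.

# crude tokenizer (lowercase, split on non-alphanumerics)
naive_tokens <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

# BM25 by direct term-by-term evaluation over a list of token vectors
naive_bm25 <- function(query_terms, doc_tokens, pos, k1 = 1.2, b = 0.75) {
  n <- length(doc_tokens)
  avgdl <- mean(lengths(doc_tokens))
  toks <- doc_tokens[[pos]]
  s <- 0
  for (t in unique(tolower(query_terms))) {
    tf <- sum(toks == t)
    if (tf == 0) next
    df <- sum(vapply(doc_tokens, function(d) t %in% d, logical(1)))
    idf <- log(1 + (n - df + 0.5) / (df + 0.5))
    s <- s + idf * tf * (k1 + 1) /
      (tf + k1 * (1 - b + b * length(toks) / avgdl))
  }
  s
}

# Concept extraction oracle for SINGLE-TOKEN concept names: a concept is in
# a document iff its name occurs among the document's tokens.
naive_concepts_single_token <- function(text, name_to_id) {
  toks <- unique(naive_tokens(text))
  sort(unname(name_to_id[names(name_to_id) %in% toks]))
}

# Leftmost-longest matching oracle by exhaustive span enumeration: list all
# token spans whose normalized form is a vocabulary surface, then greedily
# keep the longest span at the leftmost start, discarding overlaps.
naive_leftmost_longest <- function(text, surfaces) {
  toks <- naive_tokens(text)
  n <- length(toks)
  spans <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      key <- paste(toks[i:j], collapse = " ")
      if (key %in% surfaces) spans[[length(spans) + 1L]] <- c(i, j, j - i + 1L)
    }
  }
  if (length(spans) == 0L) return(character())
  sp <- do.call(rbind, spans)
  out <- character()
  pos <- 1L
  while (pos <= n) {
    here <- sp[sp[, 1] == pos, , drop = FALSE]
    if (nrow(here) == 0L) {
      pos <- pos + 1L
    } else {
      best <- here[which.max(here[, 3]), ]
      out <- c(out, paste(toks[best[1]:best[2]], collapse = " "))
      pos <- best[2] + 1L
    }
  }
  out
}

# Reciprocal rank fusion by direct per-concept evaluation of the fallback
# rule and the sum-of-reciprocals score.
naive_rrf <- function(r1, r2, train_counts, k = 60, min_train = 2) {
  concepts <- union(names(r1), names(r2))
  score <- numeric(length(concepts))
  for (i in seq_along(concepts)) {
    cid <- concepts[i]
    tc <- if (cid %in% names(train_counts)) train_counts[[cid]] else 0
    if (tc >= min_train) {
      s <- 0
      if (cid %in% names(r1)) s <- s + 1 / (k + r1[[cid]])
      if (cid %in% names(r2)) s <- s + 1 / (k + r2[[cid]])
      score[i] <- s
    } else {
      score[i] <- if (cid %in% names(r1)) 1 / (k + r1[[cid]]) else NA
    }
  }
  keep <- !is.na(score)
  concepts <- concepts[keep]; score <- score[keep]
  tie1 <- vapply(concepts, function(cid) {
    if (cid %in% names(r1)) r1[[cid]] else Inf
  }, numeric(1))
  ord <- order(-score, tie1, concepts)
  data.frame(concept_id = concepts[ord], score = score[ord],
             stringsAsFactors = FALSE)
}
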