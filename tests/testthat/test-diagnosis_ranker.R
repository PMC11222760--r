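# TF aggregation over retrieved abstracts and TF-IDF diagnosis ranking.

test_that("aggregate_tf counts abstracts containing a concept", {
  v <- concept_vocabulary(c("CX", "CY", "CZ"), c("xxx", "yyy", "zzz"))
  corpus <- data.frame(
    doc_id = c("d1", "d2", "d3"),
    title = rep("t", 3),
    # xxx in one abstract (several mentions still one abstract),
    # yyy in two, zzz in none
    body = c("xxx xxx yyy", "yyy other", "other again"),
    stringsAsFactors = FALSE)
  idx <- index_corpus(corpus, v)
  hits <- data.frame(doc_id = c("d1", "d2", "d3"), rank = 1:3)
  tal <- aggregate_tf(hits, idx)
  expect_equal(tal$tf[tal$concept_id == "CX"], 1L)
  expect_equal(tal$tf[tal$concept_id == "CY"], 2L)
  expect_false("CZ" %in% tal$concept_id)
  expect_error(aggregate_tf(hits[0, ], idx), "no retrieved abstracts")
  expect_error(aggregate_tf(data.frame(doc_id = "nope"), idx), "not in index")
})

test_that("tallies equal a brute-force recount on random hit lists", {
  rc <- random_concept_corpus(seed = 910, n_docs = 12)
  idx <- index_corpus(rc$corpus, rc$vocab)
  texts <- paste(rc$corpus$title, rc$corpus$body)
  set.seed(911)
  for (i in 1:10) {
    sel <- sample(nrow(rc$corpus), sample(2:10, 1))
    hits <- data.frame(doc_id = rc$corpus$doc_id[sel], rank = seq_along(sel))
    tal <- aggregate_tf(hits, idx)
    for (cid in unname(rc$name_to_id)) {
      nm <- names(rc$name_to_id)[match(cid, rc$name_to_id)]
      naive <- sum(vapply(texts[sel], function(tx) nm %in% naive_tokens(tx),
                          logical(1)))
      got <- tal$tf[tal$concept_id == cid]
      expect_equal(if (length(got) == 0L) 0L else got, as.integer(naive),
                   info = cid)
    }
    expect_true(all(tal$tf >= 1L & tal$tf <= length(sel)))
  }
})

# Corpus with a controllable concept df table: concept k named ck appears in
# exactly df_k documents.
df_controlled_index <- function(df_table) {
  n_docs <- max(df_table)
  ids <- sprintf("C%02d", seq_along(df_table))
  names <- sprintf("c%02d", seq_along(df_table))
  v <- concept_vocabulary(ids, names)
  body <- vapply(seq_len(n_docs), function(d) {
    paste(names[df_table >= d], collapse = " ")
  }, character(1))
  corpus <- data.frame(doc_id = sprintf("d%02d", seq_len(n_docs)),
                       title = rep("t", n_docs), body = body,
                       stringsAsFactors = FALSE)
  list(index = index_corpus(corpus, v), ids = ids)
}

test_that("rank_diagnoses orders by tf * ln(N/df) with deterministic ties", {
  ctl <- df_controlled_index(c(1, 5, 10, 2, 10, 3, 7, 4))
  idx <- ctl$index  # N = 10
  # single surviving concept is rank 1 regardless of score
  one <- rank_diagnoses(data.frame(concept_id = "C03", tf = 1L), idx)
  expect_equal(one$rank, 1L)
  expect_equal(one$concept_id, "C03")

  # equal tf, df 1 vs N/2: the rarer concept ranks first
  two <- rank_diagnoses(data.frame(concept_id = c("C02", "C01"),
                                   tf = c(3L, 3L)), idx)
  expect_equal(two$concept_id, c("C01", "C02"))

  # 8 concepts: full ordering against a hand-computed tf * ln(N/df) table
  tal <- data.frame(concept_id = ctl$ids,
                    tf = c(2L, 6L, 9L, 1L, 4L, 3L, 5L, 7L))
  hand <- data.frame(
    concept_id = ctl$ids,
    score = c(2 * log(10 / 1), 6 * log(10 / 5), 9 * log(10 / 10),
              1 * log(10 / 2), 4 * log(10 / 10), 3 * log(10 / 3),
              5 * log(10 / 7), 7 * log(10 / 4)))
  hand <- hand[order(-hand$score, -tal$tf, hand$concept_id), ]
  got <- rank_diagnoses(tal, idx)
  expect_equal(got$concept_id, hand$concept_id)
  expect_equal(got$tfidf, hand$score)
  expect_equal(got$rank, 1:8)

  # equal tfidf ties: higher tf first, then ascending concept id
  # C03 and C05 both have df = N, so tfidf = 0 for any tf
  zero <- got[got$tfidf == 0, ]
  expect_equal(zero$concept_id, c("C03", "C05"))
})

test_that("with all concept df equal, ranking reduces to tf ordering", {
  ctl <- df_controlled_index(rep(4, 6))
  tal <- data.frame(concept_id = sprintf("C%02d", 1:6),
                    tf = c(3L, 1L, 4L, 2L, 4L, 1L))
  got <- rank_diagnoses(tal, ctl$index)
  expect_equal(got$concept_id, tal$concept_id[order(-tal$tf, tal$concept_id)])
})

test_that("candidate filtering drops non-candidates but never reorders", {
  ctl <- df_controlled_index(c(1, 5, 10, 2, 10, 3, 7, 4))
  tal <- data.frame(concept_id = ctl$ids,
                    tf = c(2L, 6L, 9L, 1L, 4L, 3L, 5L, 7L))
  full <- rank_diagnoses(tal, ctl$index)
  cand <- c("C02", "C06", "C08")
  sub <- rank_diagnoses(tal, ctl$index, candidates = cand)
  expect_setequal(sub$concept_id, cand)
  expect_equal(sub$concept_id,
               full$concept_id[full$concept_id %in% cand])
  expect_equal(sub$rank, seq_len(nrow(sub)))
  expect_error(rank_diagnoses(tal, ctl$index, candidates = character()),
               "non-empty")
  expect_warning(out <- rank_diagnoses(tal, ctl$index, candidates = "C99"),
                 "no candidate")
  expect_equal(nrow(out), 0L)
})

test_that("unseen concepts score zero instead of erroring", {
  ctl <- df_controlled_index(c(2, 3))
  tal <- data.frame(concept_id = c("C01", "CUNSEEN"), tf = c(1L, 5L))
  got <- rank_diagnoses(tal, ctl$index)
  expect_equal(got$tfidf[got$concept_id == "CUNSEEN"], 0)
  expect_equal(got$concept_id[1], "C01")
  smoothed <- rank_diagnoses(tal, ctl$index, smooth = TRUE)
  n <- ctl$index$n_docs
  expect_equal(smoothed$tfidf[smoothed$concept_id == "C01"],
               1 * log((n + 1) / (2 + 1)))
})

test_that("diagnose recovers a planted diagnosis and is order-invariant", {
  w <- generate_world(world_config(n_diagnoses = 8, n_symptoms = 80,
                                   symptom_overlap = 0, filler_rate = 5,
                                   notes_max = 10, abstracts_max = 12,
                                   seed = 77))
  corpus <- w$abstracts[, c("doc_id", "title", "body")]
  idx <- index_corpus(corpus, w$vocab)
  cand <- w$diagnoses$concept_id
  notes <- w$notes[sample(nrow(w$notes), 12), ]
  top1 <- vapply(seq_len(nrow(notes)), function(i) {
    diagnose(notes$text[i], idx, w$vocab, candidates = cand)$concept_id[1]
  }, character(1))
  expect_gte(mean(top1 == notes$gold), 0.9)

  # permuting corpus insertion order leaves the output unchanged
  idx_perm <- index_corpus(corpus[rev(seq_len(nrow(corpus))), ], w$vocab)
  for (i in 1:3) {
    expect_equal(diagnose(notes$text[i], idx_perm, w$vocab, candidates = cand),
                 diagnose(notes$text[i], idx, w$vocab, candidates = cand),
                 ignore_attr = TRUE)
  }
  expect_error(diagnose("nothing recognizable whatsoever", idx, w$vocab),
               "degenerate query")
})

test_that("diagnose equals a naive rescan pipeline on a small corpus", {
  rc <- random_concept_corpus(seed = 1212, n_docs = 30, n_concepts = 15)
  idx <- index_corpus(rc$corpus, rc$vocab)
  texts <- paste(rc$corpus$title, rc$corpus$body)
  doc_tokens <- lapply(texts, naive_tokens)
  set.seed(1213)
  for (i in 1:10) {
    note <- paste(sample(c(rc$concept_names, rc$noise, "stopword"),
                         sample(3:8, 1), replace = TRUE), collapse = " ")
    q <- naive_tokens(note)
    q <- q[q %in% c(rc$concept_names)]  # naive query filtering
    if (length(q) == 0) next
    # naive retrieval: score everything, stable sort, top 5
    naive_scores <- vapply(seq_along(doc_tokens), naive_bm25, numeric(1),
                           query_terms = q, doc_tokens = doc_tokens)
    keep <- which(naive_scores > 0)
    ord <- keep[order(-naive_scores[keep], rc$corpus$doc_id[keep])]
    top <- utils::head(ord, 5)
    # naive tally + tf * ln(N/df) ranking
    n <- length(texts)
    tal_ids <- sort(unique(unlist(lapply(
      texts[top], naive_concepts_single_token, name_to_id = rc$name_to_id))))
    if (length(tal_ids) == 0) next
    tf <- vapply(tal_ids, function(cid) {
      nm <- names(rc$name_to_id)[match(cid, rc$name_to_id)]
      sum(vapply(texts[top], function(tx) nm %in% naive_tokens(tx),
                 logical(1)))
    }, numeric(1))
    df <- vapply(tal_ids, function(cid) {
      nm <- names(rc$name_to_id)[match(cid, rc$name_to_id)]
      sum(vapply(texts, function(tx) nm %in% naive_tokens(tx), logical(1)))
    }, numeric(1))
    score <- tf * log(n / df)
    exp_order <- tal_ids[order(-score, -tf, tal_ids)]
    got <- diagnose(note, idx, rc$vocab, top_n = 5)
    expect_equal(got$concept_id, exp_order, info = note)
    expect_equal(got$tfidf, unname(sort(score, decreasing = TRUE)),
                 info = note)
  }
})
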