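# Inverted index over concept-annotated abstracts + BM25 retrieval.
#
# The knowledge base of the pipeline: each abstract is stored with its
# concept dictionary (unique concepts recognized in title + body), and the
# token-level inverted index serves top-N retrieval with the practical
# Lucene-default BM25 (k1 = 1.2, b = 0.75, idf = ln(1 + (N - df + 0.5) /
# (df + 0.5))), without Lucene's length-normalization quantization.
# Corpus-wide concept document frequencies feed the diagnosis ranker's IDF
# and the abstract-coverage inclusion threshold for candidate diagnoses.

BM25_K1 <- 1.2
BM25_B <- 0.75
INDEX_FORMAT <- "litddx-index"
INDEX_VERSION <- 1L

# Shared builder: records with precomputed concept sets -> corpus_index.
build_index <- function(doc_id, title, body, concept_sets) {
  n <- length(doc_id)
  full_text <- paste(title, body)
  tok_list <- lapply(full_text, function(t) tokenize_text(t)$token)
  doc_len <- lengths(tok_list)

  postings <- new.env(hash = TRUE, parent = emptyenv())
  term <- unlist(tok_list, use.names = FALSE)
  doc_of <- rep.int(seq_len(n), doc_len)
  by_term <- split(doc_of, term)
  for (t in names(by_term)) {
    tb <- table(by_term[[t]])
    postings[[t]] <- list(doc = as.integer(names(tb)),
                          tf = as.integer(tb))
  }

  concept_df <- new.env(hash = TRUE, parent = emptyenv())
  for (cs in concept_sets) {
    for (cid in cs) {
      prev <- concept_df[[cid]]
      concept_df[[cid]] <- if (is.null(prev)) 1L else prev + 1L
    }
  }

  structure(
    list(doc_id = doc_id,
         title = title,
         body = body,
         concept_sets = concept_sets,
         doc_len = doc_len,
         avg_doc_len = mean(doc_len),
         postings = postings,
         concept_df = concept_df,
         n_docs = n),
    class = "corpus_index"
  )
}

#' Build the retrieval index over a corpus of abstracts
#'
#' Annotates every abstract with its concept dictionary (via
#' [extract_concepts()] on `title + " " + body`), builds the token-level
#' inverted index used by BM25, and tabulates corpus-wide concept document
#' frequencies (the number of abstracts whose concept set contains each
#' concept -- document frequency, not within-document counts).
#'
#' @param corpus A data frame with character columns `doc_id`, `title`,
#'   `body`; `doc_id` must be unique.
#' @param vocab A [concept_vocabulary()].
#' @return An object of class `corpus_index`.
#' @export
index_corpus <- function(corpus, vocab) {
  stopifnot(is.data.frame(corpus),
            all(c("doc_id", "title", "body") %in% names(corpus)))
  if (nrow(corpus) == 0L) stop("cannot index an empty corpus")
  doc_id <- as.character(corpus$doc_id)
  if (anyDuplicated(doc_id)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "))
  }
  title <- as.character(corpus$title)
  body <- as.character(corpus$body)
  concept_sets <- lapply(paste(title, body), extract_concepts, vocab = vocab)
  build_index(doc_id, title, body, concept_sets)
}

#' @export
print.corpus_index <- function(x, ...) {
  cat("Corpus index:", x$n_docs, "abstracts,",
      length(ls(x$postings)), "index terms,",
      length(ls(x$concept_df)), "concepts;",
      sprintf("avg doc length %.1f tokens\n", x$avg_doc_len))
  invisible(x)
}

#' Corpus-wide concept document frequency
#'
#' @param index A `corpus_index`.
#' @param concept_ids Character vector of concept ids.
#' @return Named integer vector: for each concept, the number of indexed
#'   abstracts whose concept set contains it (0 if never seen).
#' @export
concept_df <- function(index, concept_ids) {
  stopifnot(inherits(index, "corpus_index"))
  out <- vapply(as.character(concept_ids), function(cid) {
    v <- index$concept_df[[cid]]
    if (is.null(v)) 0L else v
  }, integer(1))
  out
}

bm25_idf <- function(df, n_docs) {
  log(1 + (n_docs - df + 0.5) / (df + 0.5))
}

#' BM25 relevance score of one document for a query
#'
#' Computes `sum over unique query terms t of idf(t) * tf * (k1 + 1) /
#' (tf + k1 * (1 - b + b * len_d / avgdl))` with
#' `idf(t) = ln(1 + (N - df_t + 0.5) / (df_t + 0.5))` -- the practical
#' Lucene-default BM25. The score is non-negative and 0 when no query term
#' occurs in the document.
#'
#' @param query_terms Character vector of query tokens (repeated terms count
#'   once).
#' @param doc_id A single indexed document id.
#' @param index A `corpus_index`.
#' @param k1,b BM25 parameters (Lucene defaults 1.2 and 0.75).
#' @return A single non-negative number.
#' @export
bm25_score <- function(query_terms, doc_id, index, k1 = BM25_K1, b = BM25_B) {
  stopifnot(inherits(index, "corpus_index"))
  pos <- match(as.character(doc_id), index$doc_id)
  if (is.na(pos)) stop("unknown doc_id: ", doc_id)
  terms <- unique(tolower(as.character(query_terms)))
  score <- 0
  for (t in terms) {
    p <- index$postings[[t]]
    if (is.null(p)) next
    j <- match(pos, p$doc)
    if (is.na(j)) next
    idf <- bm25_idf(length(p$doc), index$n_docs)
    tf <- p$tf[j]
    norm <- 1 - b + b * index$doc_len[pos] / index$avg_doc_len
    score <- score + idf * tf * (k1 + 1) / (tf + k1 * norm)
  }
  score
}

#' Retrieve the top-N abstracts for a filtered query
#'
#' Scores every indexed abstract with BM25 and returns the best `top_n` hits
#' with positive score, ranked by score descending; equal scores are broken
#' by ascending `doc_id` so results are deterministic. The default of 100
#' retrieved abstracts reflects that the top few documents are the most
#' likely to carry query-relevant information.
#'
#' @param index A `corpus_index`.
#' @param query Character vector of query surface forms (typically the
#'   output of [filter_query()]); internally split into tokens.
#' @param top_n Maximum number of hits (default 100).
#' @param k1,b BM25 parameters.
#' @return A data frame with columns `doc_id`, `score`, `rank` (1-based,
#'   consecutive), at most `top_n` rows, all with `score > 0`.
#' @export
search_index <- function(index, query, top_n = 100, k1 = BM25_K1, b = BM25_B) {
  stopifnot(inherits(index, "corpus_index"), top_n >= 1)
  terms <- unique(query_tokens(as.character(query)))
  if (length(terms) == 0L) {
    stop("degenerate query: no recognizable medical terms to search with")
  }
  scores <- numeric(index$n_docs)
  for (t in terms) {
    p <- index$postings[[t]]
    if (is.null(p)) next
    idf <- bm25_idf(length(p$doc), index$n_docs)
    norm <- 1 - b + b * index$doc_len[p$doc] / index$avg_doc_len
    scores[p$doc] <- scores[p$doc] + idf * p$tf * (k1 + 1) / (p$tf + k1 * norm)
  }
  keep <- which(scores > 0)
  ord <- keep[order(-scores[keep], index$doc_id[keep])]
  ord <- utils::head(ord, top_n)
  data.frame(doc_id = index$doc_id[ord],
             score = scores[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Restrict candidate diagnoses to those with enough literature coverage
#'
#' Diagnoses mentioned in very few abstracts cannot be reliably ranked from
#' retrieved literature, so an abstract-coverage inclusion threshold is
#' applied to the candidate label set (the threshold applies to candidate
#' diagnoses, not to retrieval). The default of 100 abstracts matches the
#' full-scale PubMed setting; small synthetic corpora use small thresholds.
#'
#' @param index A `corpus_index`.
#' @param candidate_ids Character vector of candidate diagnosis concept ids.
#' @param min_abstracts Minimum corpus document frequency (default 100).
#' @return The subset of `candidate_ids` with `concept_df >= min_abstracts`.
#' @export
eligible_diagnoses <- function(index, candidate_ids, min_abstracts = 100) {
  stopifnot(min_abstracts >= 0)
  ids <- as.character(candidate_ids)
  ids[concept_df(index, ids) >= min_abstracts]
}

#' Persist a corpus index to a directory
#'
#' Writes a versioned JSON manifest plus a JSONL records file (one abstract
#' per line with its precomputed concept set). [load_index()] rebuilds the
#' inverted index deterministically from the records, so a round-trip
#' reproduces identical retrieval results.
#'
#' @param index A `corpus_index`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_index <- function(index, dir) {
  stopifnot(inherits(index, "corpus_index"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = INDEX_FORMAT, version = INDEX_VERSION,
                   n_docs = index$n_docs, avg_doc_len = index$avg_doc_len)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  lines <- vapply(seq_len(index$n_docs), function(i) {
    jsonlite::toJSON(list(doc_id = index$doc_id[i],
                          title = index$title[i],
                          body = index$body[i],
                          concept_set = index$concept_sets[[i]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, file.path(dir, "records.jsonl"), useBytes = TRUE)
  invisible(dir)
}

#' Load a corpus index saved by [save_index()]
#'
#' @param dir Directory containing `manifest.json` and `records.jsonl`.
#' @return A `corpus_index`.
#' @export
load_index <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  records_path <- file.path(dir, "records.jsonl")
  if (!file.exists(manifest_path) || !file.exists(records_path)) {
    stop("not an index directory (missing manifest or records): ", dir)
  }
  manifest <- jsonlite::fromJSON(manifest_path)
  if (!identical(manifest$format, INDEX_FORMAT)) {
    stop("unrecognized index format in ", manifest_path)
  }
  if (manifest$version > INDEX_VERSION) {
    stop("index version ", manifest$version, " is newer than supported (",
         INDEX_VERSION, ")")
  }
  lines <- readLines(records_path, encoding = "UTF-8", warn = FALSE)
  recs <- lapply(lines[nzchar(lines)], jsonlite::fromJSON)
  idx <- build_index(
    doc_id = vapply(recs, function(r) r$doc_id, character(1)),
    title = vapply(recs, function(r) r$title, character(1)),
    body = vapply(recs, function(r) r$body, character(1)),
    concept_sets = lapply(recs, function(r) as.character(r$concept_set))
  )
  if (idx$n_docs != manifest$n_docs) {
    stop("index manifest reports ", manifest$n_docs, " documents but ",
         idx$n_docs, " records were read")
  }
  idx
}

#' Read a corpus from JSONL
#'
#' One JSON object per line with fields `doc_id`, `title`, `body`.
#'
#' @param path Path to a JSONL file.
#' @return A data frame with columns `doc_id`, `title`, `body`.
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("corpus file is empty: ", path)
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(doc_id = vapply(recs, function(r) as.character(r$doc_id), character(1)),
             title = vapply(recs, function(r) as.character(r$title), character(1)),
             body = vapply(recs, function(r) as.character(r$body), character(1)),
             stringsAsFactors = FALSE)
}

#' Write a corpus to JSONL
#'
#' @param corpus Data frame with columns `doc_id`, `title`, `body`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(doc_id = corpus$doc_id[i],
                          title = corpus$title[i],
                          body = corpus$body[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
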