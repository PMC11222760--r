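# From retrieved abstracts to a ranked differential diagnosis.
#
# Each concept's term frequency (TF) is the number of retrieved abstracts
# whose concept dictionary contains it -- document-level recurrence across
# the top-N list, not within-document counts. Candidates are then scored
# TF(c) * IDF(c) with IDF computed from corpus-wide concept document
# frequencies, and the highest-scoring concept is the most likely diagnosis.

#' Aggregate concept term frequencies over retrieved abstracts
#'
#' For every unique concept occurring in the concept dictionary of any
#' retrieved abstract, counts the number of retrieved abstracts containing
#' it: a concept present in exactly one abstract gets TF 1, in two abstracts
#' TF 2, and so on. All recognized concepts are kept as potential diagnoses
#' (no semantic-type pruning).
#'
#' @param hits Data frame of retrieval hits with a `doc_id` column (from
#'   [search_index()]); must be non-empty and all ids indexed.
#' @param index A `corpus_index`.
#' @return A data frame with columns `concept_id`, `tf` (integer >= 1),
#'   sorted by `concept_id`.
#' @export
aggregate_tf <- function(hits, index) {
  stopifnot(inherits(index, "corpus_index"))
  if (is.null(hits) || nrow(hits) == 0L) {
    stop("no retrieved abstracts: cannot derive candidate diagnoses")
  }
  pos <- match(as.character(hits$doc_id), index$doc_id)
  if (anyNA(pos)) {
    stop("hit doc_id not in index: ",
         paste(hits$doc_id[is.na(pos)], collapse = ", "))
  }
  tab <- table(unlist(index$concept_sets[pos], use.names = FALSE))
  data.frame(concept_id = names(tab),
             tf = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Rank candidate diagnoses by concept-level TF-IDF
#'
#' Scores every tallied concept as `tf * idf` with
#' `idf = ln(N / df)` computed over the whole indexed corpus (`df` = number
#' of indexed abstracts whose concept set contains the concept). Concepts
#' absent from the index get `df := N`, hence score 0, rather than an
#' error. With `smooth = TRUE` the guarded form `ln((N + 1) / (df + 1))` is
#' used instead.
#'
#' When `candidates` is given (evaluation mode), tallies are first
#' restricted to that label set -- e.g. concepts such as "myocardial
#' infarction" or "chest pain" are dropped when the possible ground-truth
#' diagnoses are lymphoma, coronary artery disease and gastroenteritis.
#' Restriction never reorders the surviving concepts. In open-world mode
#' (`candidates = NULL`) the full ranked concept list is returned.
#'
#' Ties on score are broken by higher `tf`, then ascending `concept_id`, so
#' ranks are deterministic (reciprocal-rank evaluation requires this).
#'
#' @param tallies Data frame with `concept_id`, `tf` (from [aggregate_tf()]).
#' @param index A `corpus_index`.
#' @param candidates Optional non-empty character vector restricting the
#'   label set.
#' @param smooth Use the smoothed IDF form (default `FALSE`).
#' @return A data frame of class `ranked_diagnoses` with columns `rank`
#'   (1-based, consecutive), `concept_id`, `tf`, `tfidf`, sorted by score
#'   descending. If every tally is filtered out, a zero-row ranking is
#'   returned with a warning (such a query scores reciprocal rank 0).
#' @export
rank_diagnoses <- function(tallies, index, candidates = NULL, smooth = FALSE) {
  stopifnot(inherits(index, "corpus_index"),
            is.data.frame(tallies),
            all(c("concept_id", "tf") %in% names(tallies)))
  if (!is.null(candidates)) {
    candidates <- as.character(candidates)
    if (length(candidates) == 0L) {
      stop("candidates, when given, must be non-empty")
    }
    tallies <- tallies[tallies$concept_id %in% candidates, , drop = FALSE]
  }
  if (nrow(tallies) == 0L) {
    warning("no candidate diagnosis survived filtering; returning an empty ",
            "ranking")
    out <- data.frame(rank = integer(), concept_id = character(),
                      tf = integer(), tfidf = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("ranked_diagnoses", "data.frame")
    return(out)
  }
  n <- index$n_docs
  df <- concept_df(index, tallies$concept_id)
  df[df == 0L] <- n  # unseen concept: no discriminative evidence, score 0
  idf <- if (smooth) log((n + 1) / (df + 1)) else log(n / df)
  tfidf <- tallies$tf * idf
  ord <- order(-tfidf, -tallies$tf, tallies$concept_id)
  out <- data.frame(rank = seq_along(ord),
                    concept_id = tallies$concept_id[ord],
                    tf = as.integer(tallies$tf[ord]),
                    tfidf = unname(tfidf[ord]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ranked_diagnoses", "data.frame")
  out
}

#' Map a patient note to a ranked differential diagnosis
#'
#' The end-to-end pipeline: the note is filtered to its recognized medical
#' terms ([filter_query()]), the filtered query retrieves the `top_n`
#' best-matching abstracts ([search_index()]), concept term frequencies are
#' aggregated over the retrieved set ([aggregate_tf()]), and candidates are
#' ranked by TF-IDF ([rank_diagnoses()]). Deterministic for a fixed index,
#' vocabulary, and note.
#'
#' @param note Free-text patient note (single string).
#' @param index A `corpus_index`.
#' @param vocab The [concept_vocabulary()] used for filtering.
#' @param candidates Optional candidate label set (evaluation mode).
#' @param top_n Number of abstracts to retrieve (default 100).
#' @param smooth Passed to [rank_diagnoses()].
#' @return A `ranked_diagnoses` data frame; rank 1 is the most likely
#'   diagnosis. Errors on a degenerate query (no recognizable medical
#'   terms) or when retrieval returns no abstracts.
#' @export
diagnose <- function(note, index, vocab, candidates = NULL, top_n = 100,
                     smooth = FALSE) {
  query <- filter_query(note, vocab)
  if (length(query) == 0L) {
    stop("degenerate query: the note contains no recognizable medical terms")
  }
  hits <- search_index(index, query, top_n = top_n)
  if (nrow(hits) == 0L) {
    stop("no retrieved abstracts: cannot derive candidate diagnoses")
  }
  tallies <- aggregate_tf(hits, index)
  out <- rank_diagnoses(tallies, index, candidates = candidates,
                        smooth = smooth)
  attr(out, "query") <- query
  out
}

#' Write a diagnosis ranking to TSV
#'
#' Columns: `rank`, `concept_id`, `preferred_name` (when a vocabulary is
#' supplied), `tf`, `tfidf`.
#'
#' @param ranking A `ranked_diagnoses` data frame.
#' @param path Output path.
#' @param vocab Optional vocabulary used to add preferred names.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, vocab = NULL) {
  out <- as.data.frame(ranking)
  if (!is.null(vocab)) {
    out$preferred_name <- vocab$concepts$preferred_name[
      match(out$concept_id, vocab$concepts$concept_id)]
    out <- out[, c("rank", "concept_id", "preferred_name", "tf", "tfidf")]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
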