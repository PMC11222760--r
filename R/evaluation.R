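# Ranking evaluation: reciprocal rank, MRR, MAP, and frequency-stratified
# MRR over training-note-count bins (long-tailed benchmarks are judged per
# frequency stratum, not only in aggregate).

# Accept a ranked_diagnoses / fused_ranking data frame, a member_ranking,
# or a named rank vector; return named integer ranks.
predicted_ranks <- function(predicted) {
  if (inherits(predicted, "member_ranking")) return(predicted$ranks)
  if (is.data.frame(predicted)) {
    stopifnot(all(c("concept_id", "rank") %in% names(predicted)))
    return(stats::setNames(as.integer(predicted$rank),
                           as.character(predicted$concept_id)))
  }
  stopifnot(is.numeric(predicted), !is.null(names(predicted)))
  stats::setNames(as.integer(predicted), names(predicted))
}

#' Reciprocal rank of a query
#'
#' `RR = 1 / rank` of the best-ranked acceptable gold diagnosis in the
#' predicted list: 1 when a gold diagnosis is at rank 1, 0.5 at rank 2, and
#' 0 when no gold diagnosis appears at all. Multiple acceptable golds (a
#' case split into several ground-truth concepts) use the best-ranked one
#' -- either concept counts as the ground truth.
#'
#' @param predicted A ranking: `ranked_diagnoses`/`fused_ranking` data
#'   frame, [member_ranking()], or named rank vector.
#' @param gold Non-empty character vector of acceptable gold concept ids.
#' @return A number in `[0, 1]`.
#' @export
reciprocal_rank <- function(predicted, gold) {
  gold <- as.character(gold)
  stopifnot(length(gold) >= 1L)
  ranks <- predicted_ranks(predicted)
  found <- ranks[names(ranks) %in% gold]
  if (length(found) == 0L) return(0)
  1 / min(found)
}

#' Mean reciprocal rank over a set of queries
#'
#' The arithmetic mean of per-query reciprocal ranks. An MRR of 1 means the
#' correct diagnosis topped the list for every query; 0 means it never
#' appeared.
#'
#' @param predictions List of rankings (one per query, any form accepted by
#'   [reciprocal_rank()]).
#' @param golds List of gold concept-id vectors, same length.
#' @return A number in `[0, 1]`.
#' @export
mean_reciprocal_rank <- function(predictions, golds) {
  stopifnot(length(predictions) == length(golds))
  if (length(predictions) == 0L) stop("no queries to evaluate")
  mean(mapply(reciprocal_rank, predictions, golds))
}

#' Average precision of one query's ranking
#'
#' Standard label-level average precision: for each gold concept found in
#' the list, precision at its rank is (number of gold concepts at or above
#' that rank) / rank; unfound golds contribute 0; AP is the mean over all
#' golds. With a single gold per query AP equals the reciprocal rank.
#'
#' @inheritParams reciprocal_rank
#' @return A number in `[0, 1]`.
#' @export
average_precision <- function(predicted, gold) {
  gold <- as.character(gold)
  stopifnot(length(gold) >= 1L)
  ranks <- predicted_ranks(predicted)
  found <- sort(unname(ranks[names(ranks) %in% gold]))
  if (length(found) == 0L) return(0)
  sum(seq_along(found) / found) / length(gold)
}

#' Mean average precision over a set of queries
#'
#' @inheritParams mean_reciprocal_rank
#' @return A number in `[0, 1]`.
#' @export
mean_average_precision <- function(predictions, golds) {
  stopifnot(length(predictions) == length(golds))
  if (length(predictions) == 0L) stop("no queries to evaluate")
  mean(mapply(average_precision, predictions, golds))
}

#' Training-note frequency bins
#'
#' The default scheme partitions non-negative training-note counts into
#' `{0}`, `(0,10]`, `(10,50]`, `(50,100]`, `(100,250]`, `(250,500]`,
#' `(500,750]`, `(750,Inf)` -- the zero-shot bin is the singleton `{0}` and
#' upper bounds are inclusive.
#'
#' @param edges Increasing numeric vector of finite bin upper edges; the
#'   first edge must be 0 (the zero-shot singleton bin).
#' @return An object of class `frequency_bins`.
#' @export
frequency_bins <- function(edges = c(0, 10, 50, 100, 250, 500, 750)) {
  stopifnot(is.numeric(edges), edges[1] == 0, !is.unsorted(edges, strictly = TRUE))
  breaks <- c(edges, Inf)
  labels <- c("0 notes",
              vapply(seq_len(length(edges) - 1L), function(i) {
                sprintf("%d-%d notes", edges[i] + 1L, edges[i + 1L])
              }, character(1)),
              sprintf(">%d notes", edges[length(edges)]))
  structure(list(breaks = breaks, labels = labels), class = "frequency_bins")
}

#' Assign training-note counts to frequency bins
#'
#' @param counts Non-negative numeric vector of training-note counts.
#' @param bins A [frequency_bins()] object.
#' @return Factor of bin labels (every count falls in exactly one bin).
#' @export
assign_bin <- function(counts, bins = frequency_bins()) {
  stopifnot(inherits(bins, "frequency_bins"), all(counts >= 0))
  # breaks are (a, b] with the first bin the singleton {0}
  idx <- findInterval(counts, bins$breaks, left.open = TRUE) + 1L
  factor(bins$labels[idx], levels = bins$labels)
}

#' MRR stratified by training-note frequency of the gold diagnosis
#'
#' Each query is assigned to the frequency bin of its primary gold
#' diagnosis's training-note count (first gold when several are
#' acceptable; missing counts default to 0), and MRR is computed per bin.
#' Bins with no queries are reported with `n = 0` and `mrr = NA`.
#'
#' @param predictions,golds As in [mean_reciprocal_rank()].
#' @param train_counts Named numeric vector of training-note counts per
#'   diagnosis concept id.
#' @param bins A [frequency_bins()].
#' @return Data frame with columns `bin`, `n`, `mrr`.
#' @export
stratified_mrr <- function(predictions, golds, train_counts,
                           bins = frequency_bins()) {
  stopifnot(length(predictions) == length(golds))
  if (length(predictions) == 0L) stop("no queries to evaluate")
  rr <- mapply(reciprocal_rank, predictions, golds)
  primary <- vapply(golds, function(g) as.character(g)[1L], character(1))
  cnt <- rep(0, length(primary))
  hit <- match(primary, names(train_counts))
  cnt[!is.na(hit)] <- unname(train_counts[hit[!is.na(hit)]])
  bin <- assign_bin(cnt, bins)
  n <- as.integer(table(bin))
  mrr <- as.numeric(tapply(rr, bin, mean))
  data.frame(bin = levels(bin), n = n, mrr = mrr,
             stringsAsFactors = FALSE)
}

#' Evaluate a set of ranked differentials against gold diagnoses
#'
#' Convenience wrapper computing per-query reciprocal ranks, MRR, MAP, and
#' (when training counts are given) the frequency-stratified MRR table.
#'
#' @param predictions List of rankings, one per query.
#' @param golds List of gold concept-id vectors.
#' @param query_ids Optional character vector of query ids (defaults to
#'   `q1, q2, ...`).
#' @param train_counts Optional named vector of training-note counts.
#' @param bins A [frequency_bins()].
#' @return A list of class `eval_report`: `per_query_rr` (named), `mrr`,
#'   `map`, and `per_bin` (data frame or `NULL`).
#' @export
evaluate_rankings <- function(predictions, golds, query_ids = NULL,
                              train_counts = NULL,
                              bins = frequency_bins()) {
  stopifnot(length(predictions) == length(golds))
  if (length(predictions) == 0L) stop("no queries to evaluate")
  if (is.null(query_ids)) query_ids <- paste0("q", seq_along(predictions))
  stopifnot(length(query_ids) == length(predictions))
  rr <- stats::setNames(mapply(reciprocal_rank, predictions, golds),
                        query_ids)
  per_bin <- if (!is.null(train_counts)) {
    stratified_mrr(predictions, golds, train_counts, bins)
  }
  structure(list(per_query_rr = rr,
                 mrr = mean(rr),
                 map = mean_average_precision(predictions, golds),
                 per_bin = per_bin),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d queries: MRR = %.4f, MAP = %.4f\n",
              length(x$per_query_rr), x$mrr, x$map))
  if (!is.null(x$per_bin)) {
    cat("MRR by training-note frequency of the gold diagnosis:\n")
    print(x$per_bin, row.names = FALSE)
  }
  invisible(x)
}
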