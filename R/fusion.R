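# Reciprocal rank fusion of the retrieval-based ranker with a second
# (supervised) ranker, with a training-count fallback rule: a supervised
# model can only be trusted on diagnoses it has actually seen in training,
# so diagnoses with too few training notes take their fused score from the
# retrieval member alone.

#' Fusion configuration
#'
#' @param k Rank-damping constant added to every rank before inversion
#'   (default 60, the near-optimal choice reported for reciprocal rank
#'   fusion; `k >= 0`).
#' @param min_train_samples Minimum training-note count for a diagnosis to
#'   use both members' ranks; below it only the retrieval member's rank is
#'   used (default 2, i.e. "more than one training sample").
#' @param unranked_policy How to treat a concept missing from a contributing
#'   member's list: `"omit"` (default; that member contributes nothing --
#'   a supervised member simply cannot rank unseen diagnoses) or
#'   `"worst_plus_one"` (impute that member's worst rank + 1).
#' @param fusion_form `"sum_of_reciprocals"` (default; the standard
#'   reciprocal-rank-fusion score `sum over members of 1 / (k + r)`) or
#'   `"reciprocal_of_sum"` (`1 / (k + sum of ranks)`).
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(k = 60,
                          min_train_samples = 2,
                          unranked_policy = c("omit", "worst_plus_one"),
                          fusion_form = c("sum_of_reciprocals",
                                          "reciprocal_of_sum")) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0,
            is.numeric(min_train_samples), length(min_train_samples) == 1L)
  structure(list(k = k,
                 min_train_samples = min_train_samples,
                 unranked_policy = match.arg(unranked_policy),
                 fusion_form = match.arg(fusion_form)),
            class = "fusion_config")
}

#' Construct a member ranking
#'
#' A member ranking is one ensemble member's ordered differential: a mapping
#' concept id -> 1-based rank. Ranks must be positive integers, unique
#' within the member (no two concepts share a rank), with no duplicated
#' concepts; gaps are allowed.
#'
#' @param x Either a named numeric vector (names = concept ids, values =
#'   ranks), or a data frame with columns `concept_id` and `rank` (a
#'   `ranked_diagnoses` or fused ranking works directly).
#' @param member_name Label for the member (used in messages).
#' @return A list of class `member_ranking` with elements `member_name` and
#'   `ranks` (named integer vector).
#' @export
member_ranking <- function(x, member_name = "member") {
  if (is.data.frame(x)) {
    stopifnot(all(c("concept_id", "rank") %in% names(x)))
    ranks <- stats::setNames(as.integer(x$rank), as.character(x$concept_id))
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    ranks <- stats::setNames(as.integer(x), names(x))
  }
  if (length(ranks) == 0L) {
    stop("member ranking '", member_name, "' is empty")
  }
  if (any(is.na(ranks)) || any(ranks < 1L)) {
    stop("member ranking '", member_name,
         "' has missing or non-positive ranks")
  }
  if (anyDuplicated(names(ranks))) {
    stop("member ranking '", member_name, "' ranks a concept twice: ",
         paste(unique(names(ranks)[duplicated(names(ranks))]), collapse = ", "))
  }
  if (anyDuplicated(ranks)) {
    stop("member ranking '", member_name, "' assigns a rank twice: ",
         paste(unique(ranks[duplicated(ranks)]), collapse = ", "))
  }
  structure(list(member_name = member_name, ranks = ranks),
            class = "member_ranking")
}

#' Read a member ranking from TSV
#'
#' Expects a header row and columns `concept_id`, `rank`.
#'
#' @param path Path to the TSV file.
#' @param member_name Label for the member (defaults to the file name).
#' @return A [member_ranking()].
#' @export
load_member_ranking <- function(path, member_name = basename(path)) {
  if (!file.exists(path)) stop("ranking file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("concept_id", "rank") %in% names(tab))) {
    stop("ranking TSV needs columns concept_id and rank: ", path)
  }
  member_ranking(tab[, c("concept_id", "rank")], member_name = member_name)
}

#' Write a member ranking to TSV
#'
#' @param member A [member_ranking()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_member_ranking <- function(member, path) {
  stopifnot(inherits(member, "member_ranking"))
  ord <- order(member$ranks)
  utils::write.table(
    data.frame(concept_id = names(member$ranks)[ord],
               rank = unname(member$ranks)[ord]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fuse two member rankings by reciprocal rank fusion
#'
#' For every concept in the union of both members' lists the fused score is
#' `sum over contributing members of 1 / (k + r(c))` (or
#' `1 / (k + sum of ranks)` under `fusion_form = "reciprocal_of_sum"`). A
#' diagnosis with fewer than `min_train_samples` training notes falls back
#' to the retrieval member alone: its score is `1 / (k + r_retrieval(c))`
#' regardless of the supervised rank, because the supervised member cannot
#' be trusted on (near-)unseen diagnoses. A fallback concept with no
#' retrieval rank has no usable evidence and is excluded with a warning.
#'
#' Concepts are returned sorted by fused score descending; ties are broken
#' by the better retrieval-member rank, then ascending concept id.
#'
#' @param retrieval A [member_ranking()] from the retrieval-based ranker
#'   (the fallback member).
#' @param supervised A [member_ranking()] from the second (supervised)
#'   ranker.
#' @param train_counts Named numeric vector: training-note count per
#'   diagnosis; missing concepts default to 0. `NULL` means all zero.
#' @param config A [fusion_config()].
#' @return A data frame of class `fused_ranking` with columns `rank`,
#'   `concept_id`, `rrf_score`.
#' @export
rrf_fuse <- function(retrieval, supervised, train_counts = NULL,
                     config = fusion_config()) {
  stopifnot(inherits(retrieval, "member_ranking"),
            inherits(supervised, "member_ranking"),
            inherits(config, "fusion_config"))
  concepts <- union(names(retrieval$ranks), names(supervised$ranks))
  if (length(concepts) == 0L) stop("no concepts to fuse")
  r1 <- unname(retrieval$ranks[match(concepts, names(retrieval$ranks))])
  r2 <- unname(supervised$ranks[match(concepts, names(supervised$ranks))])
  tc <- rep(0, length(concepts))
  if (!is.null(train_counts)) {
    hit <- match(concepts, names(train_counts))
    tc[!is.na(hit)] <- unname(train_counts[hit[!is.na(hit)]])
  }
  k <- config$k
  impute <- config$unranked_policy == "worst_plus_one"
  w1 <- if (impute) max(retrieval$ranks) + 1L else NA_integer_
  w2 <- if (impute) max(supervised$ranks) + 1L else NA_integer_

  fused <- tc >= config$min_train_samples
  # fallback concepts need a retrieval rank
  dead <- !fused & is.na(r1)
  if (any(dead)) {
    warning("excluding ", sum(dead), " concept(s) with too few training ",
            "samples and no retrieval rank: ",
            paste(utils::head(concepts[dead], 5L), collapse = ", "))
    keep <- !dead
    concepts <- concepts[keep]; r1 <- r1[keep]; r2 <- r2[keep]
    fused <- fused[keep]
  }

  e1 <- ifelse(is.na(r1), if (impute) w1 else NA, r1)
  e2 <- ifelse(is.na(r2), if (impute) w2 else NA, r2)
  score <- numeric(length(concepts))
  if (config$fusion_form == "sum_of_reciprocals") {
    s_both <- ifelse(is.na(e1), 0, 1 / (k + e1)) +
      ifelse(is.na(e2), 0, 1 / (k + e2))
  } else {
    rank_sum <- ifelse(is.na(e1), 0, e1) + ifelse(is.na(e2), 0, e2)
    s_both <- 1 / (k + rank_sum)
  }
  score[fused] <- s_both[fused]
  score[!fused] <- 1 / (k + r1[!fused])

  tie1 <- ifelse(is.na(r1), Inf, r1)
  ord <- order(-score, tie1, concepts)
  out <- data.frame(rank = seq_along(ord),
                    concept_id = concepts[ord],
                    rrf_score = score[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("fused_ranking", "data.frame")
  out
}
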