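# Concept vocabulary and dictionary-based concept recognition.
#
# The vocabulary is the closed set of recognizable medical concepts (a
# shipped stand-in for a licensed metathesaurus). Matching is exact
# dictionary lookup: greedy, left-to-right, longest-match over token
# boundaries, case- and whitespace-insensitive. No fuzzy matching, no
# stemming -- determinism is the point.

#' Tokenize text into alphanumeric tokens with character offsets
#'
#' Splits on any non-alphanumeric character, lowercases tokens, and records
#' 0-based half-open character offsets into the original text.
#'
#' @param text A single character string.
#' @return A data frame with columns `token`, `start`, `end`.
#' @keywords internal
#' @noRd
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("[A-Za-z0-9]+", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  token <- tolower(substring(text, start + 1L, start + len))
  data.frame(token = token, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

#' Normalize a surface form for dictionary lookup
#'
#' Lowercases, treats every run of non-alphanumeric characters as a single
#' separator, and joins tokens with one space. Two surface forms that differ
#' only in case, punctuation, or whitespace normalize identically.
#'
#' @param x Character vector of surface forms.
#' @return Character vector of normalized forms (`""` for forms with no
#'   alphanumeric content).
#' @export
#' @examples
#' normalize_surface(c("Kikuchi-Fujimoto  disease", "FEVER"))
normalize_surface <- function(x) {
  vapply(as.character(x), function(s) {
    paste(tokenize_text(s)$token, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a concept vocabulary
#'
#' A vocabulary maps concept identifiers (CUI-like opaque strings) to a
#' preferred name and a set of synonym surface forms. The preferred name is
#' always included among the synonyms. An inverted surface index (normalized
#' surface form -> concept ids) supports longest-match recognition; one
#' surface form may map to several concepts.
#'
#' @param concept_id Character vector of unique concept identifiers.
#' @param preferred_name Character vector, same length, of preferred names.
#' @param synonyms List of character vectors (one per concept) of synonym
#'   surface forms; the preferred name is added if absent. May be `NULL`
#'   to use preferred names only.
#' @return An object of class `concept_vocabulary`.
#' @export
#' @examples
#' v <- concept_vocabulary(c("C1", "C2"), c("fever", "abdominal pain"),
#'                         list("pyrexia", NULL))
#' extract_concepts("Fever and abdominal pain", v)
concept_vocabulary <- function(concept_id, preferred_name, synonyms = NULL) {
  concept_id <- as.character(concept_id)
  preferred_name <- as.character(preferred_name)
  stopifnot(length(concept_id) == length(preferred_name))
  if (length(concept_id) == 0L) {
    stop("vocabulary must contain at least one concept")
  }
  if (anyDuplicated(concept_id)) {
    stop("duplicate concept_id: ",
         paste(unique(concept_id[duplicated(concept_id)]), collapse = ", "))
  }
  if (is.null(synonyms)) synonyms <- vector("list", length(concept_id))
  stopifnot(length(synonyms) == length(concept_id))

  syn_sets <- vector("list", length(concept_id))
  for (i in seq_along(concept_id)) {
    syns <- unique(c(preferred_name[i], as.character(synonyms[[i]])))
    norm <- normalize_surface(syns)
    if (any(!nzchar(norm))) {
      stop("concept ", concept_id[i],
           " has a synonym that is empty after normalization")
    }
    # one representative original surface per normalized form
    syn_sets[[i]] <- syns[!duplicated(norm)]
  }
  names(syn_sets) <- concept_id

  surface_index <- new.env(hash = TRUE, parent = emptyenv())
  max_ngram <- 1L
  for (i in seq_along(concept_id)) {
    for (s in normalize_surface(syn_sets[[i]])) {
      surface_index[[s]] <- unique(c(surface_index[[s]], concept_id[i]))
      ntok <- length(strsplit(s, " ", fixed = TRUE)[[1L]])
      if (ntok > max_ngram) max_ngram <- ntok
    }
  }

  structure(
    list(concepts = data.frame(concept_id = concept_id,
                               preferred_name = preferred_name,
                               stringsAsFactors = FALSE),
         synonyms = syn_sets,
         surface_index = surface_index,
         max_ngram = max_ngram),
    class = "concept_vocabulary"
  )
}

#' @export
print.concept_vocabulary <- function(x, ...) {
  cat("Concept vocabulary:", nrow(x$concepts), "concepts,",
      length(ls(x$surface_index)), "distinct surface forms",
      sprintf("(max %d tokens)\n", x$max_ngram))
  invisible(x)
}

#' Number of concepts in a vocabulary
#' @param x A `concept_vocabulary`.
#' @return Integer concept count.
#' @export
vocabulary_size <- function(x) {
  stopifnot(inherits(x, "concept_vocabulary"))
  nrow(x$concepts)
}

#' Load a concept vocabulary from TSV or JSON
#'
#' The TSV format has a header row and three tab-separated columns:
#' `concept_id`, `preferred_name`, `synonyms` (pipe-joined surface forms;
#' may be empty to use the preferred name alone). The JSON alternative is an
#' array of objects with the same fields (`synonyms` an array of strings).
#' Rows sharing a `concept_id` are merged by synonym union; a merge with
#' conflicting preferred names is an error.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` vocabulary file.
#' @return A [concept_vocabulary()].
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    ids <- vapply(recs, function(r) as.character(r$concept_id), character(1))
    names <- vapply(recs, function(r) as.character(r$preferred_name), character(1))
    syns <- lapply(recs, function(r) as.character(r$synonyms))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (length(lines) < 1L) stop("vocabulary file is empty: ", path)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L || header[1L] != "concept_id") {
      stop("vocabulary TSV must start with a header row ",
           "'concept_id\\tpreferred_name\\tsynonyms'")
    }
    body <- lines[-1L]
    body <- body[nzchar(body)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    ids <- character(length(parts))
    names <- character(length(parts))
    syns <- vector("list", length(parts))
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p) < 2L || !nzchar(p[1L]) || !nzchar(p[2L])) {
        stop("malformed vocabulary row at line ", i + 1L, " of ", path)
      }
      ids[i] <- p[1L]
      names[i] <- p[2L]
      syn_field <- if (length(p) >= 3L) p[3L] else ""
      syn <- strsplit(syn_field, "|", fixed = TRUE)[[1L]]
      if (length(p) >= 3L && nzchar(syn_field) &&
          any(!nzchar(normalize_surface(syn)))) {
        stop("empty synonym at line ", i + 1L, " of ", path)
      }
      syns[[i]] <- syn[nzchar(syn)]
    }
  }
  # merge duplicate concept ids (synonym union); conflicting names are errors
  if (anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    for (dup in which(duplicated(ids))) {
      j <- match(ids[dup], ids)
      if (!identical(names[j], names[dup])) {
        stop("concept ", ids[dup], " appears with conflicting preferred ",
             "names: '", names[j], "' vs '", names[dup], "'")
      }
      syns[[j]] <- unique(c(syns[[j]], syns[[dup]]))
    }
    ids <- ids[keep]
    names <- names[keep]
    syns <- syns[keep]
  }
  concept_vocabulary(ids, names, syns)
}

#' Write a concept vocabulary to TSV
#'
#' Inverse of [load_vocabulary()] for the TSV format.
#'
#' @param vocab A `concept_vocabulary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "concept_vocabulary"))
  lines <- c("concept_id\tpreferred_name\tsynonyms",
             vapply(seq_len(nrow(vocab$concepts)), function(i) {
               id <- vocab$concepts$concept_id[i]
               paste(id, vocab$concepts$preferred_name[i],
                     paste(vocab$synonyms[[id]], collapse = "|"),
                     sep = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Find concept mentions in free text
#'
#' Scans the text left to right and, at each token position, takes the
#' longest vocabulary surface form that starts there (greedy
#' leftmost-longest); overlapping shorter candidates are discarded. Matching
#' is case-insensitive and insensitive to punctuation/whitespace runs.
#'
#' @param text A character string.
#' @param vocab A [concept_vocabulary()].
#' @return A data frame with one row per non-overlapping mention, in text
#'   order: `surface` (matched span as written), `start`, `end` (0-based,
#'   half-open character offsets), `norm` (normalized form), and a
#'   list-column `concept_ids` (all concepts sharing that surface form).
#' @export
find_mentions <- function(text, vocab) {
  stopifnot(inherits(vocab, "concept_vocabulary"))
  toks <- tokenize_text(text)
  n <- nrow(toks)
  idx <- vocab$surface_index
  maxn <- vocab$max_ngram
  surface <- character(); start <- integer(); end <- integer()
  norm <- character(); cids <- list()
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in seq.int(min(maxn, n - i + 1L), 1L)) {
      key <- paste(toks$token[i:(i + len - 1L)], collapse = " ")
      ids <- idx[[key]]
      if (!is.null(ids)) {
        surface <- c(surface, substring(text, toks$start[i] + 1L,
                                        toks$end[i + len - 1L]))
        start <- c(start, toks$start[i])
        end <- c(end, toks$end[i + len - 1L])
        norm <- c(norm, key)
        cids <- c(cids, list(sort(ids)))
        hit_len <- len
        break
      }
    }
    i <- i + max(hit_len, 1L)
  }
  out <- data.frame(surface = surface, start = start, end = end,
                    norm = norm, stringsAsFactors = FALSE)
  out$concept_ids <- cids
  out
}

#' Extract the unique concept set of a document
#'
#' Returns the concept dictionary of a document: the unique identifiers of
#' all vocabulary concepts whose surface forms occur in the text (greedy
#' longest-match, see [find_mentions()]). This is how each literature
#' abstract is annotated before indexing.
#'
#' @param text A character string (e.g. abstract title + body).
#' @param vocab A [concept_vocabulary()].
#' @return Sorted character vector of unique concept ids (possibly empty).
#' @export
extract_concepts <- function(text, vocab) {
  sort(unique(as.character(unlist(find_mentions(text, vocab)$concept_ids))))
}

#' Filter a clinical note down to its recognized medical terms
#'
#' Reduces a free-text patient note to a query containing only the surface
#' forms the vocabulary recognizes, in their original order; stop words,
#' filler, and other non-clinical tokens are discarded. An empty result
#' signals a degenerate query (the note contained no recognizable medical
#' terms) -- the caller decides how to handle it.
#'
#' @param note A character string.
#' @param vocab A [concept_vocabulary()].
#' @return Character vector of matched surface forms in text order
#'   (zero-length when nothing matches).
#' @export
filter_query <- function(note, vocab) {
  find_mentions(note, vocab)$surface
}

#' Split a filtered query into retrieval tokens
#'
#' @param query Character vector of surface forms (from [filter_query()]).
#' @return Character vector of lowercase tokens.
#' @keywords internal
#' @noRd
query_tokens <- function(query) {
  unlist(strsplit(normalize_surface(query), " ", fixed = TRUE),
         use.names = FALSE)
}
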