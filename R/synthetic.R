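# Synthetic benchmark generator.
#
# Emulates the structure of a literature-guided diagnosis benchmark without
# any restricted data: a long-tailed (truncated Zipf) distribution of
# abstracts and notes per diagnosis, diagnosis-specific symptom signatures
# shared between abstracts and notes, non-clinical filler tokens in notes
# (exercising query filtering), the train/valid/test split protocol for
# long-tailed note counts, and a noisy-oracle stand-in for a supervised
# ranker whose accuracy grows with training-note count and which cannot
# rank unseen diagnoses.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Truncated Zipf count profile
#'
#' Deterministic long-tailed counts: item `i` of `n` gets
#' `max(min_count, round(max_count * i^(-s)))`, so the head is heavy and
#' the tail flattens at `min_count` (with `min_count = 1` the tail is
#' singletons, mirroring long-tailed clinical datasets where hundreds of
#' diagnoses have a single note).
#'
#' @param n Number of items (rank-ordered).
#' @param s Zipf exponent (> 0).
#' @param max_count Count of the most frequent item.
#' @param min_count Floor applied to every count (default 1).
#' @return Integer vector of length `n`, non-increasing.
#' @export
zipf_counts <- function(n, s, max_count, min_count = 1) {
  stopifnot(n >= 1, s > 0, max_count >= min_count, min_count >= 0)
  pmax(as.integer(min_count), as.integer(round(max_count * seq_len(n)^(-s))))
}

#' Draw ranks from a truncated Zipf distribution
#'
#' Samples item ranks `1..k` with probability proportional to `i^(-s)`.
#'
#' @param n Number of draws.
#' @param s Zipf exponent.
#' @param k Number of items.
#' @return Integer vector of draws in `1..k`.
#' @export
rzipf <- function(n, s, k) {
  stopifnot(n >= 0, s > 0, k >= 1)
  sample.int(k, n, replace = TRUE, prob = seq_len(k)^(-s))
}

#' Synthetic world configuration
#'
#' @param n_diagnoses Number of diagnosis concepts.
#' @param n_symptoms Number of symptom concepts (must allow disjoint
#'   signatures: `n_diagnoses * signature_size <= n_symptoms`).
#' @param signature_size Symptoms in each diagnosis's signature.
#' @param abstracts_zipf,abstracts_max,abstracts_min Truncated-Zipf profile
#'   of abstracts per diagnosis (exponent, head count, floor). The floor is
#'   at least 1 so every diagnosis is retrievable.
#' @param notes_zipf,notes_max Truncated-Zipf profile of notes per
#'   diagnosis (floor 1: the tail is singleton diagnoses).
#' @param symptom_overlap Fraction of the signature shared with a paired
#'   confounder diagnosis, in `[0, 1]` (0 = fully separable diagnoses).
#' @param filler_rate Non-clinical filler tokens per note (tokens
#'   guaranteed absent from the vocabulary, so query filtering provably
#'   removes them).
#' @param note_signature_frac Fraction of the gold signature sampled into
#'   each note (at least one symptom).
#' @param n_distractors Off-signature symptoms added to each note.
#' @param seed RNG seed; identical seed + config gives identical worlds.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_diagnoses = 50,
                         n_symptoms = 400,
                         signature_size = 6,
                         abstracts_zipf = 1.5,
                         abstracts_max = 60,
                         abstracts_min = 3,
                         notes_zipf = 1.5,
                         notes_max = 400,
                         symptom_overlap = 0.2,
                         filler_rate = 10,
                         note_signature_frac = 0.8,
                         n_distractors = 1,
                         seed = 1) {
  cfg <- list(n_diagnoses = as.integer(n_diagnoses),
              n_symptoms = as.integer(n_symptoms),
              signature_size = as.integer(signature_size),
              abstracts_zipf = abstracts_zipf,
              abstracts_max = as.integer(abstracts_max),
              abstracts_min = as.integer(abstracts_min),
              notes_zipf = notes_zipf,
              notes_max = as.integer(notes_max),
              symptom_overlap = symptom_overlap,
              filler_rate = as.integer(filler_rate),
              note_signature_frac = note_signature_frac,
              n_distractors = as.integer(n_distractors),
              seed = as.integer(seed))
  stopifnot(cfg$n_diagnoses >= 1, cfg$n_symptoms >= 1,
            cfg$signature_size >= 1,
            cfg$abstracts_min >= 1, cfg$abstracts_max >= cfg$abstracts_min,
            cfg$notes_max >= 1,
            cfg$symptom_overlap >= 0, cfg$symptom_overlap <= 1,
            cfg$filler_rate >= 0,
            cfg$note_signature_frac > 0, cfg$note_signature_frac <= 1,
            cfg$n_distractors >= 0)
  if (cfg$signature_size > cfg$n_symptoms) {
    stop("infeasible config: signature_size exceeds n_symptoms")
  }
  if (cfg$n_diagnoses * cfg$signature_size > cfg$n_symptoms) {
    stop("infeasible config: need n_diagnoses * signature_size <= ",
         "n_symptoms for disjoint base signatures")
  }
  structure(cfg, class = "world_config")
}

diagnosis_cid <- function(i) sprintf("C1%05d", i)
symptom_cid <- function(j) sprintf("C2%05d", j)

#' Generate a synthetic diagnosis world
#'
#' Builds, under the configured seed: a concept vocabulary of diagnosis and
#' symptom concepts (each with one synonym beside its preferred name);
#' per-diagnosis symptom signatures, disjoint except for the configured
#' overlap between paired confounders; literature abstracts whose bodies
#' name the diagnosis plus a random subset of its signature and occasional
#' off-signature noise; patient notes containing a sample of the gold
#' signature, off-signature distractors, and out-of-vocabulary filler
#' tokens; a long-tailed train/valid/test split of the notes
#' ([split_notes()]); and training-note counts per diagnosis.
#'
#' @param cfg A [world_config()].
#' @return A list of class `synthetic_world` with elements `cfg`, `vocab`,
#'   `diagnoses`, `signatures`, `abstracts`, `notes`, `splits`,
#'   `train_counts`.
#' @export
generate_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "world_config"))
  with_seed(cfg$seed, {
    nd <- cfg$n_diagnoses
    ns <- cfg$n_symptoms

    diag_ids <- diagnosis_cid(seq_len(nd))
    diag_names <- sprintf("disease %03d", seq_len(nd))
    sym_ids <- symptom_cid(seq_len(ns))
    # symptom surface forms are token-unique (no token shared between two
    # symptoms): shared tokens would act as hidden symptom overlap at the
    # retrieval level, defeating symptom_overlap = 0
    sym_names <- sprintf("sympt%03d", seq_len(ns))
    vocab <- concept_vocabulary(
      c(diag_ids, sym_ids),
      c(diag_names, sym_names),
      c(as.list(sprintf("d%03d disorder", seq_len(nd))),
        as.list(sprintf("sgn%03d", seq_len(ns))))
    )
    # surface form of symptom j: preferred name or synonym, chosen per use
    sym_surface <- function(j) {
      ifelse(stats::runif(length(j)) < 0.5,
             sprintf("sympt%03d", j), sprintf("sgn%03d", j))
    }

    # signatures: disjoint base allocation, then paired-confounder overlap
    pool <- sample.int(ns)[seq_len(nd * cfg$signature_size)]
    signatures <- matrix(pool, nrow = nd, byrow = TRUE)
    n_shared <- round(cfg$symptom_overlap * cfg$signature_size)
    if (n_shared > 0L && nd >= 2L) {
      for (i in seq(2L, nd, by = 2L)) {
        signatures[i, seq_len(n_shared)] <- signatures[i - 1L, seq_len(n_shared)]
      }
    }

    n_abs <- zipf_counts(nd, cfg$abstracts_zipf, cfg$abstracts_max,
                         cfg$abstracts_min)
    abs_diag <- rep.int(seq_len(nd), n_abs)
    total_abs <- length(abs_diag)
    abs_title <- character(total_abs)
    abs_body <- character(total_abs)
    for (a in seq_len(total_abs)) {
      i <- abs_diag[a]
      sig <- signatures[i, ]
      keep <- sig[stats::runif(length(sig)) < 0.7]
      if (length(keep) == 0L) keep <- sig[sample.int(length(sig), 1L)]
      noise <- if (stats::runif(1) < 0.3) sample.int(ns, 1L) else integer()
      mentioned <- sample(c(keep, noise))
      abs_title[a] <- sprintf("A report of %s", diag_names[i])
      abs_body[a] <- paste(
        "We describe a patient diagnosed with", diag_names[i],
        "presenting with", paste(sym_surface(mentioned), collapse = ", "),
        "over the course of admission.")
    }
    abstracts <- data.frame(doc_id = sprintf("PM%06d", seq_len(total_abs)),
                            title = abs_title,
                            body = abs_body,
                            diagnosis_id = diag_ids[abs_diag],
                            stringsAsFactors = FALSE)

    n_notes <- zipf_counts(nd, cfg$notes_zipf, cfg$notes_max, 1L)
    note_diag <- rep.int(seq_len(nd), n_notes)
    total_notes <- length(note_diag)
    note_text <- character(total_notes)
    n_sig <- max(1L, ceiling(cfg$note_signature_frac * cfg$signature_size))
    for (q in seq_len(total_notes)) {
      i <- note_diag[q]
      sig <- signatures[i, sample.int(cfg$signature_size, n_sig)]
      distract <- if (cfg$n_distractors > 0L) {
        sample(setdiff(seq_len(ns), signatures[i, ]), cfg$n_distractors)
      } else integer()
      filler <- if (cfg$filler_rate > 0L) {
        sprintf("zz%04d", sample.int(9999L, cfg$filler_rate, replace = TRUE))
      } else character()
      chunks <- sample(c(sym_surface(c(sig, distract)), filler))
      note_text[q] <- paste("Patient presents with",
                            paste(chunks, collapse = " "))
    }
    notes <- data.frame(note_id = sprintf("N%05d", seq_len(total_notes)),
                        text = note_text,
                        gold = diag_ids[note_diag],
                        stringsAsFactors = FALSE)

    splits <- split_notes(notes)
    train_ids <- notes$gold[splits$split == "train"]
    train_counts <- stats::setNames(rep(0L, nd), diag_ids)
    tab <- table(train_ids)
    train_counts[names(tab)] <- as.integer(tab)

    structure(
      list(cfg = cfg,
           vocab = vocab,
           diagnoses = data.frame(concept_id = diag_ids,
                                  preferred_name = diag_names,
                                  n_abstracts = n_abs,
                                  n_notes = n_notes,
                                  stringsAsFactors = FALSE),
           signatures = signatures,
           abstracts = abstracts,
           notes = notes,
           splits = splits,
           train_counts = train_counts),
      class = "synthetic_world"
    )
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", nrow(x$diagnoses), "diagnoses,",
      nrow(x$abstracts), "abstracts,", nrow(x$notes), "notes",
      sprintf("(train/valid/test = %d/%d/%d)\n",
              sum(x$splits$split == "train"),
              sum(x$splits$split == "valid"),
              sum(x$splits$split == "test")))
  invisible(x)
}

#' Split notes into train/valid/test under the long-tailed protocol
#'
#' Per diagnosis: with exactly 1 note, that note goes to test (zero-shot
#' diagnoses exist only at test time); with 2-4 notes, exactly 1 note is
#' reserved for test and the rest train (no validation); with >= 5 notes, a
#' 70:15:15 train/valid/test split is applied, taking `floor(0.15 * m)` for
#' validation, `max(1, floor(0.15 * m))` for test (rounding favors test so
#' every such diagnosis is testable), remainder to train. Assignment within
#' a diagnosis is a seeded shuffle (the caller's RNG state, or `seed`).
#'
#' @param notes Data frame with columns `note_id`, `gold`.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Data frame with columns `note_id`, `split` (one of `"train"`,
#'   `"valid"`, `"test"`), one row per input note.
#' @export
split_notes <- function(notes, seed = NULL) {
  stopifnot(is.data.frame(notes), all(c("note_id", "gold") %in% names(notes)))
  assign_one <- function(idx) {
    m <- length(idx)
    idx <- if (m > 1L) sample(idx) else idx
    if (m == 1L) {
      split <- "test"
    } else if (m < 5L) {
      split <- c("test", rep("train", m - 1L))
    } else {
      n_valid <- floor(0.15 * m)
      n_test <- max(1L, floor(0.15 * m))
      split <- c(rep("test", n_test), rep("valid", n_valid),
                 rep("train", m - n_valid - n_test))
    }
    data.frame(note_id = notes$note_id[idx], split = split,
               stringsAsFactors = FALSE)
  }
  run <- function() {
    parts <- lapply(split(seq_len(nrow(notes)), notes$gold), assign_one)
    out <- do.call(rbind, parts)
    out <- out[match(notes$note_id, out$note_id), ]
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Default accuracy profile of the noisy-oracle supervised ranker
#'
#' The probability that the oracle places the gold diagnosis at rank 1 as a
#' function of its training-note count: 0 for unseen diagnoses, then
#' `min(0.98, n / (n + 2))` -- weak with 1-3 notes, strong for well
#' represented diagnoses (the qualitative pattern of a fine-tuned
#' supervised classifier).
#'
#' @param n Non-negative training-note counts.
#' @return Probabilities in `[0, 1]`.
#' @export
default_oracle_quality <- function(n) {
  ifelse(n <= 0, 0, pmin(0.98, n / (n + 2)))
}

#' Noisy-oracle stand-in for a supervised ranker
#'
#' Emulates a fine-tuned supervised classifier: only diagnoses with at
#' least one training note are ranked at all (a supervised model cannot
#' make predictions for unseen diagnoses); with probability
#' `quality(train_count(gold))` the gold diagnosis is placed at rank 1,
#' otherwise at a rank drawn uniformly from `[2, n_diagnoses]`; the
#' remaining trained diagnoses fill the other ranks in random order.
#' Stochastic -- seed the RNG for reproducibility.
#'
#' @param gold Gold diagnosis concept id of the note being ranked.
#' @param world A `synthetic_world`.
#' @param quality Function mapping training-note count to the probability
#'   of ranking the gold first (default [default_oracle_quality()]).
#' @return A [member_ranking()] over the trained diagnoses (the gold is
#'   absent when it has no training notes), or `NULL` when no diagnosis has
#'   training data.
#' @export
noisy_oracle_ranker <- function(gold, world, quality = default_oracle_quality) {
  stopifnot(inherits(world, "synthetic_world"))
  tc <- world$train_counts
  trained <- names(tc)[tc >= 1L]
  if (length(trained) == 0L) return(NULL)
  nd <- nrow(world$diagnoses)
  if (gold %in% trained) {
    p <- quality(tc[[gold]])
    stopifnot(p >= 0, p <= 1)
    gold_rank <- if (stats::runif(1) < p || nd < 2L) {
      1L
    } else {
      sample(2:nd, 1L)
    }
    others <- setdiff(trained, gold)
    others <- if (length(others) > 1L) sample(others) else others
    slots <- setdiff(seq_len(length(trained) + 1L), gold_rank)
    ranks <- stats::setNames(c(gold_rank, slots[seq_along(others)]),
                             c(gold, others))
  } else {
    perm <- if (length(trained) > 1L) sample(trained) else trained
    ranks <- stats::setNames(seq_along(perm), perm)
  }
  member_ranking(ranks, member_name = "noisy_oracle")
}

#' Write a synthetic world to a directory of plain-text files
#'
#' Emits `corpus.jsonl`, `vocab.tsv`, `notes.jsonl`, `gold.tsv`,
#' `counts.tsv`, and `splits.tsv` -- the file formats consumed by the
#' command-line interface.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus_jsonl(world$abstracts[, c("doc_id", "title", "body")],
                     file.path(dir, "corpus.jsonl"))
  write_vocabulary(world$vocab, file.path(dir, "vocab.tsv"))
  lines <- vapply(seq_len(nrow(world$notes)), function(i) {
    jsonlite::toJSON(list(note_id = world$notes$note_id[i],
                          text = world$notes$text[i],
                          gold = world$notes$gold[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, file.path(dir, "notes.jsonl"), useBytes = TRUE)
  utils::write.table(world$notes[, c("note_id", "gold")],
                     file.path(dir, "gold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(concept_id = names(world$train_counts),
                                count = unname(world$train_counts)),
                     file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$splits, file.path(dir, "splits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read patient notes from JSONL
#'
#' One object per line with fields `note_id`, `text`, and optionally `gold`.
#'
#' @param path Path to a JSONL file.
#' @return Data frame with columns `note_id`, `text`, and `gold` (NA when
#'   absent).
#' @export
read_notes_jsonl <- function(path) {
  if (!file.exists(path)) stop("notes file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("notes file is empty: ", path)
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    note_id = vapply(recs, function(r) as.character(r$note_id), character(1)),
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    gold = vapply(recs, function(r) {
      if (is.null(r$gold)) NA_character_ else as.character(r$gold)
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Read per-diagnosis training-note counts from TSV
#'
#' Expects a header and columns `concept_id`, `count`.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector.
#' @export
read_train_counts <- function(path) {
  if (!file.exists(path)) stop("train-counts file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("concept_id", "count") %in% names(tab))) {
    stop("train-counts TSV needs columns concept_id and count: ", path)
  }
  stats::setNames(as.integer(tab$count), as.character(tab$concept_id))
}
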