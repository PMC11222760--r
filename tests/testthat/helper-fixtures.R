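# Fixtures built in code. Nothing is read from disk except files the tests
# themselves write to tempdir().

# Small handcrafted clinical vocabulary covering the worked examples.
clinical_vocab <- function() {
  concept_vocabulary(
    concept_id = c("C0863106", "C0030353", "C0015967", "C0497365",
                   "C0018563", "C3665599", "C0343405", "C1457887",
                   "C0000737", "C0030193"),
    preferred_name = c("afebrile seizures", "papilledema", "fever",
                       "rashes", "hand", "skin", "Kikuchi-Fujimoto disease",
                       "symptoms", "abdominal pain", "pain"),
    synonyms = list(NULL, NULL, "pyrexia", "rash", NULL, NULL,
                    "histiocytic necrotizing lymphadenitis", NULL, NULL,
                    NULL)
  )
}

# Random single-token-concept world for oracle-equivalence tests: concept
# names c01..cK; documents are random bags of concept names plus noise.
random_concept_corpus <- function(seed, n_docs = 10, n_concepts = 8,
                                  noise_words = 5) {
  set.seed(seed)
  ids <- sprintf("X%03d", seq_len(n_concepts))
  names <- sprintf("c%02d", seq_len(n_concepts))
  vocab <- concept_vocabulary(ids, names)
  name_to_id <- stats::setNames(ids, names)
  noise <- sprintf("n%02d", seq_len(noise_words))
  docs <- vapply(seq_len(n_docs), function(i) {
    len <- sample(3:12, 1)
    paste(sample(c(names, noise), len, replace = TRUE), collapse = " ")
  }, character(1))
  corpus <- data.frame(doc_id = sprintf("d%02d", seq_len(n_docs)),
                       title = sprintf("title %02d", seq_len(n_docs)),
                       body = docs, stringsAsFactors = FALSE)
  list(vocab = vocab, corpus = corpus, name_to_id = name_to_id,
       concept_names = names, noise = noise)
}

# Memoized worlds shared by the heavier tests (built once per run).
.world_cache <- new.env(parent = emptyenv())
cached_world <- function(key, cfg) {
  if (is.null(.world_cache[[key]])) {
    w <- generate_world(cfg)
    idx <- index_corpus(w$abstracts[, c("doc_id", "title", "body")], w$vocab)
    test_ids <- w$splits$note_id[w$splits$split == "test"]
    .world_cache[[key]] <- list(
      world = w, index = idx,
      test_notes = w$notes[w$notes$note_id %in% test_ids, ])
  }
  .world_cache[[key]]
}

# Fully separable world: no shared signature symptoms, no filler tokens.
clean_world <- function() {
  cached_world("clean", world_config(symptom_overlap = 0, filler_rate = 0,
                                     notes_max = 800, seed = 11))
}

# Confusable world with a supervised noisy oracle worth fusing with.
fusion_world <- function() {
  cached_world("fusion", world_config(symptom_overlap = 0.4,
                                      notes_max = 2000, seed = 23))
}

diagnose_all <- function(bundle, notes = bundle$test_notes) {
  lapply(notes$text, diagnose, index = bundle$index,
         vocab = bundle$world$vocab,
         candidates = bundle$world$diagnoses$concept_id)
}
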