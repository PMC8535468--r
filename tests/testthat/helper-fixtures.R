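# Shared fixture knowledge base, built once per test run.
kb_file <- tempfile("fixture_kb_", fileext = ".json")
build_fixture_kb(kb_file)
kb <- load_fixture_kb(kb_file)

# Build a candidate-phrase list from one phrase string (tokens split on
# whitespace, tagged and lemmatized like the pipeline does).
make_candidate <- function(phrase, line = 1L, start = 0L) {
  toks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  pos <- pos_tag_tokens(toks)
  list(tokens = toks, lemmas = lemmatize_tokens(toks, pos), pos_tags = pos,
       n = length(toks), line = line, start = start,
       end = start + length(toks) - 1L,
       normalized = normalize_phrase(toks))
}

# Fully resolve one phrase against a backend and return its vote.
vote_for <- function(phrase, backend, threshold = 0.7, concept_limit = 8L) {
  recs <- extract_semantics(list(make_candidate(phrase)), backend,
                            threshold = threshold,
                            concept_limit = concept_limit)
  if (length(recs) == 0L) return(NULL)
  majority_vote(label_semantic_types(flatten_semantic_types(recs[[1]])))
}

# Independent brute-force vote oracle: count each class, find the maximum,
# and among maximal classes pick the one whose label occurs first.
oracle_vote_winner <- function(labels) {
  labels <- labels[labels != "NONE"]
  if (length(labels) == 0L) return(NA_character_)
  classes <- c("Problem", "Treatment", "Test")
  counts <- sapply(classes, function(cl) length(which(labels == cl)))
  best <- classes[counts == max(counts)]
  for (lab in labels) if (lab %in% best) return(lab)
}

# Run the pipeline over a generated corpus and pool predictions/gold.
score_corpus <- function(corpus, mode = "exact", threshold = 0.7) {
  pred <- list()
  for (id in names(corpus$notes)) {
    anns <- run_pipeline(read_document(corpus$notes[[id]], id),
                         corpus$backend, approx_threshold = threshold)
    pred <- c(pred, anns)
  }
  gold <- unlist(unname(corpus$gold), recursive = FALSE)
  evaluate_annotations(pred, gold, mode = mode)
}
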