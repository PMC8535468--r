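# Offline test world: a miniature Metathesaurus-style fixture knowledge
# base seeded from published worked examples (a term with multiple
# concepts, a concept with two semantic types, out-of-dictionary "NONE"
# semantic types), plus a seeded generator for synthetic clinical notes
# with gold annotations, so every pipeline stage is testable without
# access to the licensed UMLS or i2b2 corpora.

.concept <- function(cui, name, root_source, types) {
  list(cui = cui, name = name, root_source = root_source,
       semantic_types = lapply(types, function(t)
         list(tui = t[[1]], name = t[[2]])))
}

#' Build the bundled fixture knowledge base
#'
#' Writes a JSON fixture knowledge base whose content reproduces the
#' reference lookups used throughout the test suite: "coronary artery
#' disease" resolving first to C0010054 "Coronary Arteriosclerosis";
#' "trout" resolving to C0041200 "Salmo trutta" with semantic type T013
#' "Fish" in the "Living Beings" group; "stress" splitting into four
#' concepts, one of which ("Stress bismuth subsalicylate") carries two
#' semantic types; and "beta blockers", "heart rate" and "increased heart
#' rate", whose flattened semantic-type sequences are the canonical
#' worked examples for the three vote rules (rule 1 majority, rule 2
#' three-way tie, rule 3 two-way tie with NONE entries). A handful of
#' further clinical terms round out the vocabulary for corpus generation.
#'
#' @param out_path Where to write the JSON file.
#' @return `out_path`, invisibly.
#' @export
build_fixture_kb <- function(out_path) {
  DS <- c("T047", "Disease or Syndrome")
  FI <- c("T033", "Finding")
  CA <- c("T201", "Clinical Attribute")
  OC <- c("T109", "Organic Chemical")
  PS <- c("T121", "Pharmacologic Substance")
  PF <- c("T046", "Pathologic Function")
  IP <- c("T037", "Injury or Poisoning")
  MD <- c("T074", "Medical Device")
  SS <- c("T184", "Sign or Symptom")
  DP <- c("T060", "Diagnostic Procedure")
  MB <- c("T048", "Mental or Behavioral Dysfunction")
  FSH <- c("T013", "Fish")
  NONE <- c("T000", "NONE")

  terms <- list(
    list(term = "coronary artery disease", concepts = list(
      .concept("C0010054", "Coronary Arteriosclerosis", "MTH", list(DS)),
      .concept("C1956346", "Coronary Artery Disease", "MDR", list(DS)),
      .concept("C3842888", "Coronary artery disease, unspecified", "ICD10CM", list(DS)),
      .concept("C0010072", "Coronary artery atheroma", "SNOMEDCT_US", list(OC)),
      .concept("C2228002", "Coronary artery calcium score", "LNC", list(CA)))),
    list(term = "trout", concepts = list(
      .concept("C0041200", "Salmo trutta", "NCBI", list(FSH)))),
    list(term = "stress", concepts = list(
      .concept("C0038435", "Stress", "MTH", list(FI)),
      .concept("C0038443", "Stress, Psychological", "MSH", list(MB)),
      .concept("C0015260", "Exercise stress test", "MTH", list(DP)),
      .concept("C0700590", "Stress bismuth subsalicylate", "MTH", list(OC, PS)))),
    list(term = "beta blockers", concepts = list(
      .concept("C0001645", "Adrenergic beta-Antagonists", "MSH", list(PS)),
      .concept("C0304516", "beta-Blocker preparation", "SNOMEDCT_US", list(OC)),
      .concept("C0340298", "Beta blocker overdose", "SNOMEDCT_US", list(PF)),
      .concept("C1504365", "beta-Blocking agent product", "RXNORM", list(OC)),
      .concept("C3842100", "Beta blocker response measurement", "LNC", list(CA)),
      .concept("C0563213", "Beta blocker poisoning", "SNOMEDCT_US", list(IP)),
      .concept("C1142113", "Beta-adrenergic blocking agent", "NDFRT", list(PS)))),
    list(term = "heart rate", concepts = list(
      .concept("C0018810", "Heart rate", "MTH", list(CA)),
      .concept("C2926602", "Heart rate pattern", "LNC", list(CA)),
      .concept("C0425583", "Heart rate normal", "SNOMEDCT_US", list(FI)),
      .concept("C0558925", "Heart rate satisfactory", "SNOMEDCT_US", list(FI)),
      .concept("C1305738", "Heart rate monitor", "SNOMEDCT_US", list(MD)),
      .concept("C1320488", "Heart rate alarm device", "SNOMEDCT_US", list(MD)))),
    list(term = "increased heart rate", concepts = list(
      .concept("C0039231", "Tachycardia", "MTH", list(FI)),
      .concept("C0425680", "Heart rate increased", "SNOMEDCT_US", list(FI)),
      .concept("C2111793", "Heart rate increase amount", "LNC", list(CA)),
      .concept("C2926603", "Increased heart rate measure", "LNC", list(CA)),
      .concept("C0520888", "Heart rate fast", "SNOMEDCT_US", list(FI)),
      .concept("C3263722", "Rate of heart increase", "LNC", list(CA)),
      .concept("C0750906", "Rapid heart beat", "MDR", list(FI)),
      .concept("C4050476", "Heart rate response", "LNC", list(CA, NONE, NONE)))),
    list(term = "pelvic fracture", concepts = list(
      .concept("C0016664", "Fracture of pelvis", "MTH", list(IP)))),
    list(term = "blood pressure", concepts = list(
      .concept("C0005823", "Blood Pressure", "MTH", list(CA)))),
    list(term = "chest pain", concepts = list(
      .concept("C0008031", "Chest Pain", "MTH", list(SS)))),
    list(term = "aspirin", concepts = list(
      .concept("C0004057", "Aspirin", "MTH", list(OC, PS)))),
    list(term = "atherosclerosis", concepts = list(
      .concept("C0004153", "Atherosclerosis", "MTH", list(DS))))
  )

  entity_types <- list(
    list(tui = "T013", abbreviation = "LIVB", expanded_form = "Living Beings"),
    list(tui = "T047", abbreviation = "DISO", expanded_form = "Disorders"),
    list(tui = "T033", abbreviation = "DISO", expanded_form = "Disorders"),
    list(tui = "T046", abbreviation = "DISO", expanded_form = "Disorders"),
    list(tui = "T048", abbreviation = "DISO", expanded_form = "Disorders"),
    list(tui = "T037", abbreviation = "DISO", expanded_form = "Disorders"),
    list(tui = "T184", abbreviation = "DISO", expanded_form = "Disorders"),
    list(tui = "T109", abbreviation = "CHEM", expanded_form = "Chemicals & Drugs"),
    list(tui = "T121", abbreviation = "CHEM", expanded_form = "Chemicals & Drugs"),
    list(tui = "T201", abbreviation = "PHYS", expanded_form = "Physiology"),
    list(tui = "T074", abbreviation = "DEVI", expanded_form = "Devices"),
    list(tui = "T060", abbreviation = "PROC", expanded_form = "Procedures"),
    list(tui = "T000", abbreviation = "MISC", expanded_form = "Miscellaneous"))

  jsonlite::write_json(list(terms = terms, entity_types = entity_types),
                       out_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(out_path)
}

# distractor templates: every word is a stopword, verb, adjective or
# adverb, so boundary filtering discards all distractor-only n-grams and
# the generated corpus has no unplanted matchable content
.distractor_pool <- list(
  before = c("she was very", "they did have", "he went away with",
             "it was not so", "we will see", "was doing very well with",
             "did not have any", "had been quite"),
  after = c("again yesterday", "once more today", "so very well",
            "but was fine", "and was well again", "now and then",
            "very well overnight", "too once more"))

#' Specification for a synthetic annotated corpus
#'
#' @param seed Integer seed; the corpus is byte-identical for a fixed
#'   spec.
#' @param n_documents Number of notes.
#' @param concepts_per_doc Planted concept phrases per note (one per
#'   line).
#' @param vocabulary Optional data.frame with columns `phrase` and
#'   `category`; defaults to every classifiable term of the fixture
#'   knowledge base, with the category derived by running the
#'   dictionary-mapped majority vote on the knowledge base itself.
#' @param typo_rate Fraction of planted phrases receiving a single-character
#'   substitution, to exercise approximate matching (default 0).
#' @param category_weights Optional named weights (`problem`, `treatment`,
#'   `test`) to plant a class-imbalanced corpus.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(seed = 1L, n_documents = 3L, concepts_per_doc = 5L,
                        vocabulary = NULL, typo_rate = 0,
                        category_weights = NULL) {
  stopifnot(n_documents >= 0, concepts_per_doc >= 0,
            typo_rate >= 0, typo_rate <= 1)
  structure(list(seed = as.integer(seed), n_documents = as.integer(n_documents),
                 concepts_per_doc = as.integer(concepts_per_doc),
                 vocabulary = vocabulary, typo_rate = typo_rate,
                 category_weights = category_weights),
            class = "corpus_spec")
}

# derive the plantable vocabulary from a backend: every term that ends up
# with a vote winner, labelled with that winner
.kb_vocabulary <- function(backend, concept_limit = 8L) {
  phrases <- character(0)
  cats <- character(0)
  for (term in kb_terms(backend)) {
    cons <- search_concepts(backend, term, limit = concept_limit)
    names_flat <- unlist(lapply(cons$cui, function(cui)
      search_semantic_types(backend, cui)$name), use.names = FALSE)
    vote <- majority_vote(label_semantic_types(names_flat))
    if (!is.na(vote$winner)) {
      phrases <- c(phrases, term)
      cats <- c(cats, tolower(vote$winner))
    }
  }
  data.frame(phrase = phrases, category = cats, stringsAsFactors = FALSE)
}

.inject_typo <- function(phrase) {
  words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  long <- which(nchar(words) >= 4)
  if (length(long) == 0L) return(phrase)
  wi <- long[sample.int(length(long), 1L)]
  w <- words[wi]
  ci <- sample(2:(nchar(w) - 1L), 1L)
  repl <- sample(setdiff(letters, substr(w, ci, ci)), 1L)
  substr(w, ci, ci) <- repl
  words[wi] <- w
  paste(words, collapse = " ")
}

#' Generate a synthetic annotated corpus
#'
#' Builds (or reuses) the fixture knowledge base, then writes `n_documents`
#' synthetic notes. Each note line embeds one vocabulary phrase between
#' distractor fragments drawn from a stopword/verb/adverb-heavy template
#' pool, so word-boundary filtering is genuinely exercised and, with the
#' default vocabulary, nothing outside the planted phrases can match the
#' knowledge base. Gold annotations record each planted span with the
#' category the majority vote derives from the knowledge base itself, in
#' i2b2 `.con` coordinates.
#'
#' @param spec A [corpus_spec()].
#' @param out_dir Optional directory; when given, writes `note_<i>.txt`,
#'   `note_<i>.con` and `fixture_kb.json` there.
#' @param kb_path Optional path to an existing fixture KB JSON to use
#'   instead of building the bundled one.
#' @return A list with `notes` (named character vector of note texts),
#'   `gold` (named list of annotation lists), `kb_path` and `backend`.
#' @export
generate_synthetic_corpus <- function(spec = corpus_spec(), out_dir = NULL,
                                      kb_path = NULL) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (is.null(kb_path)) {
    kb_path <- if (is.null(out_dir)) tempfile(fileext = ".json")
               else file.path(out_dir, "fixture_kb.json")
    if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                      recursive = TRUE)
    build_fixture_kb(kb_path)
  }
  backend <- load_fixture_kb(kb_path)
  vocab <- spec$vocabulary %||% .kb_vocabulary(backend)
  if (nrow(vocab) == 0L && spec$concepts_per_doc > 0L)
    stop("corpus spec: empty vocabulary")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  weights <- rep(1, nrow(vocab))
  if (!is.null(spec$category_weights)) {
    w <- spec$category_weights[vocab$category]
    weights <- ifelse(is.na(w), 0, w)
  }

  notes <- character(0)
  gold <- list()
  for (d in seq_len(spec$n_documents)) {
    doc_id <- sprintf("note_%02d", d)
    lines <- character(0)
    anns <- list()
    for (li in seq_len(spec$concepts_per_doc)) {
      vi <- if (nrow(vocab) == 1L) 1L
            else sample.int(nrow(vocab), 1L, prob = weights)
      phrase <- vocab$phrase[vi]
      if (spec$typo_rate > 0 && stats::runif(1) < spec$typo_rate)
        phrase <- .inject_typo(phrase)
      pre <- strsplit(sample(.distractor_pool$before, 1L), " ")[[1]]
      post <- strsplit(sample(.distractor_pool$after, 1L), " ")[[1]]
      ptoks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
      lines <- c(lines, paste(c(pre, ptoks, post, "."), collapse = " "))
      anns[[length(anns) + 1L]] <- list(
        doc_id = doc_id, text = phrase, line = li,
        start = length(pre), end = length(pre) + length(ptoks) - 1L,
        category = vocab$category[vi])
    }
    notes[doc_id] <- paste(lines, collapse = "\n")
    gold[[doc_id]] <- anns
  }

  if (!is.null(out_dir)) {
    for (doc_id in names(notes)) {
      writeLines(notes[[doc_id]], file.path(out_dir, paste0(doc_id, ".txt")))
      write_i2b2_con(gold[[doc_id]], file.path(out_dir, paste0(doc_id, ".con")))
    }
  }
  list(notes = notes, gold = gold, kb_path = kb_path, backend = backend)
}
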