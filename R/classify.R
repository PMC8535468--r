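# Concept classification: semantic types are mapped to the Problem /
# Treatment / Test domains through three fixed semantic-type dictionaries,
# and a term's category is the argmax of the mapped label counts, with
# positional tie-breaking over the ordered label sequence.

#' Default semantic-type dictionaries
#'
#' The three semantic-type dictionaries that define the clinical domains:
#' 12 problem types, 9 treatment types and 7 test types. Matching against
#' them is case-insensitive. The sets are pairwise disjoint, so each
#' semantic type contributes exactly one label. Callers may supply their
#' own dictionaries to [label_semantic_types()] for domain extension.
#'
#' @return A list with character-vector elements `problem`, `treatment`,
#'   `test`.
#' @export
semantic_dictionaries <- function() {
  list(
    problem = c(
      "Disease or Syndrome", "Sign or Symptom", "Finding",
      "Pathologic Function", "Mental or Behavioral Dysfunction",
      "Injury or Poisoning", "Cell or Molecular Dysfunction",
      "Congenital Abnormality", "Acquired Abnormality", "Neoplastic Process",
      "Anatomic Abnormality", "virus/bacterium"),
    treatment = c(
      "Therapeutic or Preventive Procedure", "Organic Chemical",
      "Pharmacologic Substance", "Biomedical and Dental material",
      "Antibiotic", "Clinical Drug", "Steroid", "Drug Delivery Device",
      "Medical Device"),
    test = c(
      "Tissue", "Cell", "Laboratory or Test Result", "Laboratory Procedure",
      "diagnostic procedure", "Clinical Attribute", "Body Substance")
  )
}

.check_dicts <- function(dicts) {
  stopifnot(all(c("problem", "treatment", "test") %in% names(dicts)))
  low <- lapply(dicts[c("problem", "treatment", "test")], tolower)
  if (anyDuplicated(unlist(low)))
    stop("semantic dictionaries must be pairwise disjoint")
  low
}

#' Map semantic-type names to domain labels
#'
#' Maps each semantic-type name to `"Problem"`, `"Treatment"` or `"Test"`
#' by case-insensitive lookup in the dictionaries, or to `"NONE"` when the
#' name is in no dictionary.
#'
#' @param names Ordered character vector of semantic-type names.
#' @param dicts Dictionaries as returned by [semantic_dictionaries()].
#' @return Character vector of labels, same length and order as `names`.
#' @examples
#' label_semantic_types(c("Pharmacologic Substance", "Finding", "Tissue"))
#' @export
label_semantic_types <- function(names, dicts = semantic_dictionaries()) {
  low <- .check_dicts(dicts)
  vapply(tolower(names), function(nm) {
    if (nm %in% low$problem) "Problem"
    else if (nm %in% low$treatment) "Treatment"
    else if (nm %in% low$test) "Test"
    else "NONE"
  }, character(1), USE.NAMES = FALSE)
}

#' Majority vote over an ordered label sequence
#'
#' Tallies the domain labels of a term (after removing `NONE` entries) and
#' picks the winning domain:
#' \describe{
#'   \item{rule 1}{a unique maximum count wins outright;}
#'   \item{rule 2}{a three-way tie goes to the domain whose label appears
#'     earliest in the sequence;}
#'   \item{rule 3}{a two-way tie above the third domain goes to whichever
#'     of the two tied domains appears earliest in the sequence.}
#' }
#' An empty (or all-`NONE`) sequence yields no winner and
#' `rule_applied = "unclassified"`. The tie-breaks are positional, which is
#' why label order — concept preference order, then within-concept order —
#' is preserved all the way down the pipeline.
#'
#' @param labels Character vector with values in
#'   `{"Problem", "Treatment", "Test", "NONE"}`.
#' @return A `clin_vote` list: `labels` (with `NONE` removed), `counts`
#'   (named integer vector over the three domains), `winner` (a domain or
#'   `NA`), `rule_applied` (`"rule1"`, `"rule2"`, `"rule3"` or
#'   `"unclassified"`).
#' @examples
#' majority_vote(c("Treatment", "Treatment", "Problem", "Treatment",
#'                 "Test", "Problem", "Treatment"))
#' @export
majority_vote <- function(labels) {
  classes <- c("Problem", "Treatment", "Test")
  if (!all(labels %in% c(classes, "NONE")))
    stop("labels must be drawn from {Problem, Treatment, Test, NONE}")
  labels <- labels[labels != "NONE"]
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (length(labels) == 0L) {
    return(structure(list(labels = labels, counts = counts,
                          winner = NA_character_,
                          rule_applied = "unclassified"),
                     class = "clin_vote"))
  }
  top <- max(counts)
  tied <- classes[counts == top]
  if (length(tied) == 1L) {
    winner <- tied
    rule <- "rule1"
  } else {
    winner <- labels[labels %in% tied][1L]  # earliest-occurring tied label
    rule <- if (length(tied) == 3L) "rule2" else "rule3"
  }
  structure(list(labels = labels, counts = counts, winner = winner,
                 rule_applied = rule),
            class = "clin_vote")
}

#' @export
print.clin_vote <- function(x, ...) {
  cat(sprintf("<vote: %s (%s); Problem=%d Treatment=%d Test=%d>\n",
              if (is.na(x$winner)) "unclassified" else x$winner,
              x$rule_applied, x$counts["Problem"], x$counts["Treatment"],
              x$counts["Test"]))
  invisible(x)
}

#' Classify one term record
#'
#' Maps the record's flattened semantic-type sequence to domain labels and
#' applies the majority vote. Terms whose semantic types are all outside
#' the dictionaries produce no annotation.
#'
#' @param record A fully populated term record (see [extract_semantics()]).
#' @param dicts Semantic-type dictionaries.
#' @return A concept annotation — `list(text, line, start, end, category,
#'   vote, concepts, match)` with `category` in
#'   `{"problem", "treatment", "test"}` — or `NULL` when unclassifiable.
#' @export
classify_term <- function(record, dicts = semantic_dictionaries()) {
  labels <- label_semantic_types(flatten_semantic_types(record), dicts)
  vote <- majority_vote(labels)
  if (is.na(vote$winner)) return(NULL)
  cand <- record$candidate
  list(text = paste(cand$tokens, collapse = " "),
       line = cand$line, start = cand$start, end = cand$end,
       category = tolower(vote$winner), vote = vote,
       concepts = record$concepts, match = record$match)
}

# keep exact-mode annotations over approximate ones, then higher match
# similarity, then longer spans, then leftmost; greedy over same-line
# token-range overlaps. Ranking similarity before length stops a fuzzy
# match of a phrase plus an adjacent function word from displacing the
# tight span it contains (exact matches all score 1, so the longest exact
# span still wins among exact hits).
.resolve_overlaps <- function(annotations) {
  if (length(annotations) <= 1L) return(annotations)
  mode_rank <- vapply(annotations, function(a)
    if (identical(a$match$mode, "exact")) 0L else 1L, integer(1))
  score <- vapply(annotations, function(a) a$match$score, numeric(1))
  len <- vapply(annotations, function(a) a$end - a$start + 1L, integer(1))
  line <- vapply(annotations, function(a) a$line, integer(1))
  start <- vapply(annotations, function(a) a$start, integer(1))
  ord <- order(mode_rank, -score, -len, line, start)
  kept <- list()
  for (i in ord) {
    a <- annotations[[i]]
    clash <- any(vapply(kept, function(k) {
      k$line == a$line && k$start <= a$end && a$start <= k$end
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- a
  }
  line <- vapply(kept, function(a) a$line, integer(1))
  start <- vapply(kept, function(a) a$start, integer(1))
  kept[order(line, start)]
}

#' Run the full extraction-and-classification pipeline on one note
#'
#' Tokenizes and tags the note, enumerates n-gram candidates, filters them
#' by word boundary, resolves the surviving phrases against the knowledge
#' backend (hybrid exact-plus-approximate matching), classifies each
#' matched term by dictionary-mapped majority vote, and emits one
#' annotation per classified occurrence. Overlapping spans are resolved in
#' favour of exact matches, then longer spans (composite concepts carry
#' more meaning than their parts), then leftmost position. Deterministic
#' for fixed inputs and configuration.
#'
#' @param doc A `clin_document` from [read_document()], or raw note text.
#' @param backend A knowledge backend.
#' @param dicts Semantic-type dictionaries.
#' @param ngram_max Maximum candidate phrase length in tokens (default 4).
#' @param concept_limit Concepts kept per term (default 8).
#' @param approx_threshold Approximate-match threshold, or `NULL` for
#'   exact-only matching (default 0.7).
#' @param stopwords Stopword list for boundary filtering.
#' @return A list of concept annotations (see [classify_term()]), ordered
#'   by position.
#' @export
run_pipeline <- function(doc, backend, dicts = semantic_dictionaries(),
                         ngram_max = 4L, concept_limit = 8L,
                         approx_threshold = 0.7,
                         stopwords = clin_stopwords()) {
  if (is.character(doc)) doc <- read_document(doc)
  stopifnot(inherits(doc, "clin_document"))
  candidates <- candidate_phrases(doc, n_max = ngram_max)
  retained <- identify_word_boundaries(candidates, stopwords)
  # keep only tight spans: edge punctuation tokens would inflate the span
  # without changing the normalized lookup form
  retained <- retained[vapply(retained, function(p) {
    nzchar(p$normalized) &&
      !grepl("^[[:punct:]]+$", p$tokens[1]) &&
      !grepl("^[[:punct:]]+$", p$tokens[p$n])
  }, logical(1))]
  unique_phrases <- deduplicate_phrases(retained)
  records <- extract_semantics(unique_phrases, backend,
                               threshold = approx_threshold,
                               concept_limit = concept_limit)
  decisions <- list()
  for (rec in records) {
    ann <- classify_term(rec, dicts)
    if (!is.null(ann)) decisions[[rec$term]] <- list(record = rec, ann = ann)
  }
  annotations <- list()
  for (p in retained) {
    dec <- decisions[[p$normalized]]
    if (is.null(dec)) next
    a <- dec$ann
    a$text <- paste(p$tokens, collapse = " ")
    a$line <- p$line
    a$start <- p$start
    a$end <- p$end
    annotations[[length(annotations) + 1L]] <- a
  }
  anns <- .resolve_overlaps(annotations)
  lapply(anns, function(a) { a$doc_id <- doc$doc_id; a })
}

#' Annotations as a data.frame
#'
#' @param annotations A list of concept annotations.
#' @return A data.frame with columns `doc_id`, `text`, `line`, `start`,
#'   `end`, `category`, `rule`, `mode`.
#' @export
annotations_to_df <- function(annotations) {
  if (length(annotations) == 0L) {
    return(data.frame(doc_id = character(0), text = character(0),
                      line = integer(0), start = integer(0),
                      end = integer(0), category = character(0),
                      rule = character(0), mode = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    doc_id = vapply(annotations, function(a) a$doc_id %||% "", ""),
    text = vapply(annotations, function(a) a$text, ""),
    line = vapply(annotations, function(a) as.integer(a$line), 1L),
    start = vapply(annotations, function(a) as.integer(a$start), 1L),
    end = vapply(annotations, function(a) as.integer(a$end), 1L),
    category = vapply(annotations, function(a) a$category, ""),
    rule = vapply(annotations, function(a)
      if (is.null(a$vote)) NA_character_ else a$vote$rule_applied, ""),
    mode = vapply(annotations, function(a)
      if (is.null(a$match)) NA_character_ else a$match$mode, ""),
    stringsAsFactors = FALSE)
}
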