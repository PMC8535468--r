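# Metathesaurus-style knowledge backend. A backend answers three lookups —
# term -> concepts, CUI -> semantic types, TUI -> semantic group (entity
# type) — plus approximate string matching over its term inventory. The
# default implementation is an offline fixture loaded from a JSON file; a
# thin client for a UTS-style terminology REST service implements the same
# contract (see kb_remote.R).

#' @name knowledge-backend
#' @title Knowledge-backend lookup contract
#' @description
#' Generic lookup operations every knowledge backend implements. Results
#' are deterministic for a fixed backend snapshot and ordered by the
#' backend's native preference order (for a Metathesaurus this mirrors how
#' source vocabularies tag their preferred concept names first).
#' @param backend A knowledge backend (see [load_fixture_kb()],
#'   [kb_remote()]).
#' @param term A nonempty normalized phrase.
#' @param cui A concept unique identifier (`C` + digits).
#' @param tui A semantic-type unique identifier (`T` + digits).
#' @param limit Maximum number of concepts to return (default 8, the point
#'   past which retrieval accuracy plateaus on annotated clinical corpora).
#' @param threshold Minimum trigram-Jaccard similarity in `[0.6, 1]`.
NULL

#' @rdname knowledge-backend
#' @return `search_concepts()`: a data.frame with columns `cui`, `name`,
#'   `root_source` — at most `limit` rows, empty when the term is unknown.
#' @export
search_concepts <- function(backend, term, limit = 8L) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  if (!is.numeric(limit) || limit < 1) stop("`limit` must be >= 1")
  UseMethod("search_concepts")
}

#' @rdname knowledge-backend
#' @return `search_semantic_types()`: a data.frame with columns `tui`,
#'   `name` (1 to 5 rows for a known CUI, empty for an unknown one).
#' @export
search_semantic_types <- function(backend, cui) {
  stopifnot(is.character(cui), length(cui) == 1L, grepl("^C[0-9]+$", cui))
  UseMethod("search_semantic_types")
}

#' @rdname knowledge-backend
#' @return `search_entity_type()`: a one-row data.frame with columns
#'   `abbreviation`, `expanded_form`; unknown TUIs yield the sentinel
#'   `("UNKNOWN", "Unknown")`.
#' @export
search_entity_type <- function(backend, tui) {
  stopifnot(is.character(tui), length(tui) == 1L, grepl("^T[0-9]+$", tui))
  UseMethod("search_entity_type")
}

#' @rdname knowledge-backend
#' @return `approximate_candidates()`: a data.frame with columns
#'   `matched_term`, `score` — every term entry with similarity at or above
#'   `threshold`, sorted by score descending, ties broken lexicographically.
#' @export
approximate_candidates <- function(backend, term, threshold = 0.7) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  .check_threshold(threshold)
  UseMethod("approximate_candidates")
}

#' @rdname knowledge-backend
#' @return `kb_terms()`: the backend's term inventory (character vector),
#'   where available.
#' @export
kb_terms <- function(backend) UseMethod("kb_terms")

.check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0.6 || threshold > 1.0) {
    stop("`threshold` must be a single number in [0.6, 1.0]")
  }
}

#' Character-trigram Jaccard similarity
#'
#' Similarity between two strings as the Jaccard index of their sets of
#' character trigrams (lowercased; strings shorter than three characters
#' contribute themselves as a single gram). Symmetric, in `[0, 1]`, equal
#' strings score exactly 1.
#'
#' @param a,b Strings to compare.
#' @return A number in `[0, 1]`.
#' @export
trigram_similarity <- function(a, b) {
  ga <- .trigrams(tolower(a))
  gb <- .trigrams(tolower(b))
  if (length(ga) == 0L && length(gb) == 0L) return(1)
  length(intersect(ga, gb)) / length(union(ga, gb))
}

.trigrams <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(character(0))
  if (n < 3L) return(s)
  unique(substring(s, 1:(n - 2L), 3:n))
}

# ---- fixture backend ------------------------------------------------------

#' Load a fixture knowledge base from a JSON file
#'
#' The fixture file is a miniature Metathesaurus snapshot with schema
#' `{terms: [{term, concepts: [{cui, name, root_source, semantic_types:
#' [{tui, name}]}]}], entity_types: [{tui, abbreviation, expanded_form}]}`.
#' Concept order within a term is the preference order used throughout the
#' pipeline. The loader validates the schema: every concept needs a CUI and
#' 1–5 semantic types, a CUI may not repeat within a term or be redefined
#' with different semantic types elsewhere, and entity-type TUIs must be
#' unique.
#'
#' @param path Path to the JSON fixture file.
#' @return A backend of class `clin_kb_fixture`.
#' @seealso [build_fixture_kb()] to generate the bundled fixture.
#' @export
load_fixture_kb <- function(path) {
  stopifnot(file.exists(path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  terms <- list()
  cui_types <- list()
  for (trec in raw$terms %||% list()) {
    term <- trec$term
    if (is.null(term) || !nzchar(term))
      stop("fixture KB: term record without a 'term' field")
    if (!is.null(terms[[term]]))
      stop(sprintf("fixture KB: duplicate term entry '%s'", term))
    cuis_here <- character(0)
    concepts <- lapply(trec$concepts %||% list(), function(con) {
      if (is.null(con$cui) || !grepl("^C[0-9]+$", con$cui))
        stop(sprintf("fixture KB: concept under '%s' with missing/malformed cui", term))
      sty <- lapply(con$semantic_types %||% list(), function(st) {
        if (is.null(st$tui) || is.null(st$name))
          stop(sprintf("fixture KB: semantic type without tui/name under cui %s", con$cui))
        list(tui = st$tui, name = st$name)
      })
      if (length(sty) < 1L || length(sty) > 5L)
        stop(sprintf("fixture KB: cui %s must carry 1..5 semantic types", con$cui))
      list(cui = con$cui, name = con$name %||% "",
           root_source = con$root_source %||% "", semantic_types = sty)
    })
    for (con in concepts) {
      if (con$cui %in% cuis_here)
        stop(sprintf("fixture KB: duplicate cui %s under term '%s'", con$cui, term))
      cuis_here <- c(cuis_here, con$cui)
      known <- cui_types[[con$cui]]
      if (!is.null(known) && !identical(known, con$semantic_types))
        stop(sprintf("fixture KB: cui %s redefined with different semantic types", con$cui))
      cui_types[[con$cui]] <- con$semantic_types
    }
    terms[[term]] <- concepts
  }
  entity_types <- list()
  for (et in raw$entity_types %||% list()) {
    if (is.null(et$tui) || !is.null(entity_types[[et$tui]]))
      stop("fixture KB: missing or duplicate entity-type tui")
    entity_types[[et$tui]] <- list(abbreviation = et$abbreviation %||% "UNKNOWN",
                                   expanded_form = et$expanded_form %||% "Unknown")
  }
  structure(list(terms = terms, cui_types = cui_types,
                 entity_types = entity_types, path = path),
            class = c("clin_kb_fixture", "clin_kb"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.clin_kb_fixture <- function(x, ...) {
  cat(sprintf("<fixture knowledge base: %d terms, %d concepts, %d entity types>\n",
              length(x$terms), length(x$cui_types), length(x$entity_types)))
  invisible(x)
}

.empty_concepts <- function() {
  data.frame(cui = character(0), name = character(0),
             root_source = character(0), stringsAsFactors = FALSE)
}

#' @export
search_concepts.clin_kb_fixture <- function(backend, term, limit = 8L) {
  cons <- backend$terms[[term]]
  if (is.null(cons)) return(.empty_concepts())
  cons <- cons[seq_len(min(length(cons), as.integer(limit)))]
  data.frame(cui = vapply(cons, `[[`, "", "cui"),
             name = vapply(cons, `[[`, "", "name"),
             root_source = vapply(cons, `[[`, "", "root_source"),
             stringsAsFactors = FALSE)
}

#' @export
search_semantic_types.clin_kb_fixture <- function(backend, cui) {
  sty <- backend$cui_types[[cui]]
  if (is.null(sty)) {
    return(data.frame(tui = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(tui = vapply(sty, `[[`, "", "tui"),
             name = vapply(sty, `[[`, "", "name"),
             stringsAsFactors = FALSE)
}

#' @export
search_entity_type.clin_kb_fixture <- function(backend, tui) {
  et <- backend$entity_types[[tui]]
  if (is.null(et)) et <- list(abbreviation = "UNKNOWN", expanded_form = "Unknown")
  data.frame(abbreviation = et$abbreviation, expanded_form = et$expanded_form,
             stringsAsFactors = FALSE)
}

#' @export
kb_terms.clin_kb_fixture <- function(backend) names(backend$terms)

#' @export
approximate_candidates.clin_kb_fixture <- function(backend, term,
                                                   threshold = 0.7) {
  entries <- names(backend$terms)
  scores <- vapply(entries, trigram_similarity, numeric(1), b = term,
                   USE.NAMES = FALSE)
  keep <- scores >= threshold
  entries <- entries[keep]
  scores <- scores[keep]
  ord <- order(-scores, entries)
  data.frame(matched_term = entries[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}

# ---- hybrid matching ------------------------------------------------------

#' Hybrid exact-plus-approximate term matching
#'
#' Matches each normalized phrase against the backend in two passes: exact
#' lookup first, then approximate matching for the phrases exact lookup
#' missed, and returns the union of both lists. Exact matching alone leaves
#' much information unmatched (misspellings, inflectional variants);
#' approximate matching alone sacrifices precision; the hybrid keeps both.
#'
#' @param backend A knowledge backend.
#' @param terms Character vector of normalized phrases.
#' @param threshold Approximate-match similarity threshold in `[0.6, 1]`
#'   (default 0.7). Set to `NULL` to disable the approximate pass.
#' @return A named list mapping each matched phrase to a term match:
#'   `list(query, matched_term, mode, score)` with `mode` `"exact"`
#'   (score 1) or `"approximate"` (best-scoring entry at or above the
#'   threshold). Phrases with neither kind of match are absent.
#' @export
hybrid_match <- function(backend, terms, threshold = 0.7) {
  if (!is.null(threshold)) .check_threshold(threshold)
  out <- list()
  for (term in unique(terms[nzchar(terms)])) {
    if (nrow(search_concepts(backend, term, limit = 1L)) > 0L) {
      out[[term]] <- list(query = term, matched_term = term,
                          mode = "exact", score = 1.0)
    } else if (!is.null(threshold)) {
      cand <- approximate_candidates(backend, term, threshold)
      if (nrow(cand) > 0L) {
        out[[term]] <- list(query = term, matched_term = cand$matched_term[1],
                            mode = "approximate", score = cand$score[1])
      }
    }
  }
  out
}
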