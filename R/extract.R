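# Semantic extraction pipeline: boundary-validated phrases are matched to
# knowledge-base terms, then each term is expanded to its concepts, each
# concept to its semantic types, and each semantic type to its semantic
# group (entity type). Records only ever shrink after term finding — a
# lookup that comes back empty drops the record rather than erroring, so
# the pipeline stays total on sparse knowledge bases.

#' Find knowledge-base terms for candidate phrases
#'
#' Matches each candidate phrase against the backend with hybrid
#' exact-plus-approximate matching. The surface form is queried first; if
#' it misses, the lemmatized form is queried, and the record notes which
#' form hit. Phrases with no match of either kind are omitted; input order
#' is preserved.
#'
#' @param phrases List of boundary-validated candidate phrases.
#' @param backend A knowledge backend.
#' @param threshold Approximate-match threshold, or `NULL` for exact-only
#'   matching.
#' @return A list of term records: `list(term, candidate, match,
#'   lookup_form)`.
#' @export
find_terms <- function(phrases, backend, threshold = 0.7) {
  out <- list()
  for (p in phrases) {
    if (!nzchar(p$normalized)) next
    m <- hybrid_match(backend, p$normalized, threshold)[[p$normalized]]
    lookup <- "surface"
    if (is.null(m)) {
      lemma_form <- normalize_phrase(p$lemmas)
      if (nzchar(lemma_form) && !identical(lemma_form, p$normalized)) {
        m <- hybrid_match(backend, lemma_form, threshold)[[lemma_form]]
        lookup <- "lemma"
      }
    }
    if (is.null(m)) next
    out[[length(out) + 1L]] <- list(term = p$normalized, candidate = p,
                                    match = m, lookup_form = lookup)
  }
  out
}

#' Resolve concepts for term records
#'
#' Attaches to each record the first `concept_limit` concepts of its
#' matched knowledge-base term, in the backend's preference order. A record
#' whose lookup unexpectedly returns no concept is dropped.
#'
#' @param records Term records from [find_terms()].
#' @param backend A knowledge backend.
#' @param concept_limit Maximum concepts kept per term (default 8).
#' @return Records with a `concepts` data.frame (`cui`, `name`,
#'   `root_source`).
#' @export
identify_concepts <- function(records, backend, concept_limit = 8L) {
  out <- list()
  for (rec in records) {
    cons <- search_concepts(backend, rec$match$matched_term,
                            limit = concept_limit)
    if (nrow(cons) == 0L) next
    rec$concepts <- cons
    out[[length(out) + 1L]] <- rec
  }
  out
}

#' Resolve semantic types for each concept
#'
#' Attaches the semantic types (1–5 per concept) of every resolved
#' concept. A concept with no semantic type in the backend is dropped with
#' a warning; a record left with no concepts is dropped entirely.
#'
#' @param records Records from [identify_concepts()].
#' @param backend A knowledge backend.
#' @return Records with `semantic_types`, a list of data.frames (`tui`,
#'   `name`) parallel to the rows of `concepts`.
#' @export
identify_semantic_types <- function(records, backend) {
  out <- list()
  for (rec in records) {
    sty <- lapply(rec$concepts$cui, function(cui)
      search_semantic_types(backend, cui))
    keep <- vapply(sty, nrow, integer(1)) > 0L
    if (any(!keep)) {
      warning(sprintf("dropping %d concept(s) of term '%s' with no semantic type",
                      sum(!keep), rec$term))
    }
    if (!any(keep)) next
    rec$concepts <- rec$concepts[keep, , drop = FALSE]
    rec$semantic_types <- sty[keep]
    out[[length(out) + 1L]] <- rec
  }
  out
}

#' Resolve entity types (semantic groups) for each semantic type
#'
#' Maps every semantic type to its single semantic group. Unknown TUIs get
#' the sentinel `("UNKNOWN", "Unknown")` record; entity types are carried
#' as metadata and do not drive classification.
#'
#' @param records Records from [identify_semantic_types()].
#' @param backend A knowledge backend.
#' @return Records with `entity_types`, a list (parallel to
#'   `semantic_types`) of data.frames (`abbreviation`, `expanded_form`).
#' @export
identify_entity_types <- function(records, backend) {
  lapply(records, function(rec) {
    rec$entity_types <- lapply(rec$semantic_types, function(sty) {
      do.call(rbind, lapply(sty$tui, function(tui)
        search_entity_type(backend, tui)))
    })
    rec
  })
}

#' Flattened semantic-type name sequence of a term record
#'
#' Concatenates semantic-type names in concept order, then within-concept
#' order. This flat sequence is the breakdown the majority vote operates
#' on, and its order matters because tie-breaking is positional.
#'
#' @param record A fully populated term record.
#' @return Character vector of semantic-type names.
#' @export
flatten_semantic_types <- function(record) {
  unlist(lapply(record$semantic_types, function(sty) sty$name),
         use.names = FALSE) %||% character(0)
}

#' Full semantic extraction for candidate phrases
#'
#' Convenience composition of [find_terms()], [identify_concepts()],
#' [identify_semantic_types()] and [identify_entity_types()]; identical to
#' applying the four steps in sequence.
#'
#' @param phrases Boundary-validated candidate phrases.
#' @param backend A knowledge backend.
#' @param threshold Approximate-match threshold (`NULL` = exact only).
#' @param concept_limit Maximum concepts per term.
#' @return Fully populated term records.
#' @export
extract_semantics <- function(phrases, backend, threshold = 0.7,
                              concept_limit = 8L) {
  records <- find_terms(phrases, backend, threshold)
  records <- identify_concepts(records, backend, concept_limit)
  records <- identify_semantic_types(records, backend)
  identify_entity_types(records, backend)
}
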