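# Optional client for a UTS-style terminology REST service. It implements
# the same lookup contract as the fixture backend so the two are
# interchangeable, but it needs network access and an API key, so nothing
# in the test suite depends on it. Responses are cached per process keyed
# by (operation, query); cached and uncached answers are identical because
# the service is treated as a fixed snapshot for a given release.

#' Remote terminology-service backend
#'
#' Builds a backend that answers the lookup contract against a UTS-style
#' REST service (`/content/<release>/CUI/...`, `/search/<release>`,
#' `/semantic-network/<release>/TUI/...`). Network failures raise a
#' condition of class `kb_io_error`, distinct from an empty "no match"
#' result, so callers can retry.
#'
#' @param base_url Service root URL.
#' @param api_key API key string (or set `UTS_API_KEY` in the environment).
#' @param release Release tag interpolated into request paths.
#' @return A backend of class `clin_kb_remote`.
#' @export
kb_remote <- function(base_url, api_key = Sys.getenv("UTS_API_KEY"),
                      release = "current") {
  stopifnot(is.character(base_url), nzchar(base_url))
  structure(list(base_url = sub("/$", "", base_url), api_key = api_key,
                 release = release, cache = new.env(parent = emptyenv())),
            class = c("clin_kb_remote", "clin_kb"))
}

.remote_get <- function(backend, path, query) {
  key <- paste(path, query, sep = "\r")
  if (!is.null(backend$cache[[key]])) return(backend$cache[[key]])
  url <- sprintf("%s/%s?%s&apiKey=%s", backend$base_url, path, query,
                 backend$api_key)
  ans <- tryCatch(
    jsonlite::fromJSON(url, simplifyVector = FALSE),
    error = function(e) {
      stop(structure(class = c("kb_io_error", "error", "condition"),
                     list(message = paste("terminology service unreachable:",
                                          conditionMessage(e)),
                          call = sys.call(-1))))
    })
  backend$cache[[key]] <- ans
  ans
}

#' @export
search_concepts.clin_kb_remote <- function(backend, term, limit = 8L) {
  ans <- .remote_get(backend, sprintf("search/%s", backend$release),
                     sprintf("string=%s&searchType=exact", utils::URLencode(term)))
  res <- ans$result$results %||% list()
  res <- res[seq_len(min(length(res), as.integer(limit)))]
  data.frame(cui = vapply(res, function(r) r$ui %||% "", ""),
             name = vapply(res, function(r) r$name %||% "", ""),
             root_source = vapply(res, function(r) r$rootSource %||% "", ""),
             stringsAsFactors = FALSE)
}

#' @export
search_semantic_types.clin_kb_remote <- function(backend, cui) {
  ans <- tryCatch(
    .remote_get(backend, sprintf("content/%s/CUI/%s", backend$release, cui), ""),
    kb_io_error = function(e) stop(e))
  sty <- ans$result$semanticTypes %||% list()
  data.frame(tui = vapply(sty, function(s) sub(".*/", "", s$uri %||% ""), ""),
             name = vapply(sty, function(s) s$name %||% "", ""),
             stringsAsFactors = FALSE)
}

#' @export
search_entity_type.clin_kb_remote <- function(backend, tui) {
  ans <- .remote_get(backend,
                     sprintf("semantic-network/%s/TUI/%s", backend$release, tui), "")
  grp <- ans$result$semanticTypeGroup %||% list()
  data.frame(abbreviation = grp$abbreviation %||% "UNKNOWN",
             expanded_form = grp$expandedForm %||% "Unknown",
             stringsAsFactors = FALSE)
}

#' @export
kb_terms.clin_kb_remote <- function(backend) {
  stop("the remote backend does not expose its full term inventory")
}

#' @export
approximate_candidates.clin_kb_remote <- function(backend, term,
                                                  threshold = 0.7) {
  ans <- .remote_get(backend, sprintf("search/%s", backend$release),
                     sprintf("string=%s&searchType=approximate",
                             utils::URLencode(term)))
  res <- ans$result$results %||% list()
  entries <- vapply(res, function(r) r$name %||% "", "")
  scores <- vapply(entries, trigram_similarity, numeric(1), b = term,
                   USE.NAMES = FALSE)
  keep <- scores >= threshold
  entries <- entries[keep]
  scores <- scores[keep]
  ord <- order(-scores, entries)
  data.frame(matched_term = entries[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}
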