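# Document preprocessing: tokenization, candidate n-gram generation and
# word-boundary filtering. Clinical notes are line-oriented, so both a
# newline and sentence-final punctuation end a sentence, while annotation
# offsets stay (line, token-within-line) as in the i2b2 convention:
# 1-based lines, 0-based tokens.

#' English stopword list shipped with the package
#'
#' A frozen copy of the standard English stopword list used by common NLP
#' toolkits, shipped in the package so boundary filtering is reproducible
#' across toolkit versions.
#'
#' @param file Optional path to an alternative newline-delimited list.
#' @return Character vector of lowercase stopwords.
#' @export
clin_stopwords <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "stopwords_en.txt", package = "clinconcept",
                        mustWork = TRUE)
  }
  readLines(file, encoding = "UTF-8", warn = FALSE)
}

# split one whitespace-delimited chunk into tokens, peeling leading and
# trailing punctuation but keeping abbreviation-internal periods ("q.d.")
# and unit slashes ("mg/dL") inside the token
.split_chunk <- function(chunk) {
  out <- character(0)
  while (nchar(chunk) > 0 && grepl("^[[:punct:]]", chunk) &&
         !grepl("^[[:alnum:]]", chunk)) {
    out <- c(out, substr(chunk, 1, 1))
    chunk <- substr(chunk, 2, nchar(chunk))
  }
  trailing <- character(0)
  while (nchar(chunk) > 1 && grepl("[[:punct:]]$", chunk)) {
    if (grepl("^([[:alpha:]]\\.)+$", chunk)) break  # abbreviation like q.d.
    trailing <- c(substr(chunk, nchar(chunk), nchar(chunk)), trailing)
    chunk <- substr(chunk, 1, nchar(chunk) - 1)
  }
  c(out, if (nchar(chunk)) chunk, trailing)
}

#' Tokenize raw note text into sentences of tokens
#'
#' Splits a UTF-8 clinical note into sentences of tokens. Lines are split on
#' whitespace; punctuation is peeled off word edges into tokens of its own
#' (keeping abbreviation periods and unit slashes intact); each newline ends
#' a sentence, as does sentence-final punctuation (`.`, `!`, `?`) within a
#' line. Token indices count all tokens of the physical line, 0-based; line
#' numbering is 1-based.
#'
#' @param text A single string (may contain newlines, may be empty).
#' @return A list of sentences; each sentence is a data.frame with columns
#'   `surface`, `line` and `tok`.
#' @examples
#' tokenize("The patient has a pelvic fracture.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(list())
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sentences <- list()
  for (li in seq_along(lines)) {
    chunks <- strsplit(trimws(lines[li]), "[[:space:]]+")[[1]]
    chunks <- chunks[nzchar(chunks)]
    if (length(chunks) == 0L) next
    toks <- unlist(lapply(chunks, .split_chunk), use.names = FALSE)
    df <- data.frame(surface = toks, line = li,
                     tok = seq_along(toks) - 1L,
                     stringsAsFactors = FALSE)
    ends <- which(df$surface %in% c(".", "!", "?"))
    bounds <- unique(c(ends, nrow(df)))
    start <- 1L
    for (b in bounds) {
      if (b >= start) {
        sentences[[length(sentences) + 1L]] <- df[start:b, , drop = FALSE]
        start <- b + 1L
      }
    }
  }
  sentences
}

#' Read a note into an annotated document
#'
#' Tokenizes the text and attaches Penn Treebank tags and lemmas to every
#' token.
#'
#' @param text Raw note text (single string).
#' @param doc_id Document identifier carried through to annotations.
#' @return An object of class `clin_document`: a list with `doc_id`, `text`
#'   and `sentences`, each sentence a data.frame with columns `surface`,
#'   `lemma`, `pos`, `line`, `tok`.
#' @export
read_document <- function(text, doc_id = "doc") {
  sents <- tokenize(text)
  sents <- lapply(sents, function(s) {
    s$pos <- pos_tag_tokens(s$surface)
    s$lemma <- lemmatize_tokens(s$surface, s$pos)
    s[, c("surface", "lemma", "pos", "line", "tok")]
  })
  structure(list(doc_id = doc_id, text = text, sentences = sents),
            class = "clin_document")
}

#' @export
print.clin_document <- function(x, ...) {
  cat(sprintf("<clin_document '%s': %d sentence(s), %d token(s)>\n",
              x$doc_id, length(x$sentences),
              sum(vapply(x$sentences, nrow, integer(1)))))
  invisible(x)
}

#' Normalize a phrase for knowledge-base lookup
#'
#' Lowercases, drops punctuation-only tokens at the phrase edges and
#' collapses internal whitespace to single spaces.
#'
#' @param tokens Character vector of phrase tokens.
#' @return A single normalized string (may be empty for punctuation-only
#'   input).
#' @export
normalize_phrase <- function(tokens) {
  is_punct <- grepl("^[[:punct:]]+$", tokens)
  keep <- rep(TRUE, length(tokens))
  i <- 1L
  while (i <= length(tokens) && is_punct[i]) { keep[i] <- FALSE; i <- i + 1L }
  i <- length(tokens)
  while (i >= 1L && is_punct[i]) { keep[i] <- FALSE; i <- i - 1L }
  tolower(paste(tokens[keep], collapse = " "))
}

.make_candidate <- function(sent, from, to) {
  idx <- from:to
  list(tokens = sent$surface[idx],
       lemmas = sent$lemma[idx],
       pos_tags = sent$pos[idx],
       n = to - from + 1L,
       line = sent$line[from],
       start = sent$tok[from],
       end = sent$tok[to],
       normalized = normalize_phrase(sent$surface[idx]))
}

#' Generate contiguous n-gram candidate phrases
#'
#' Enumerates every contiguous window of 1 to `n_max` tokens within one
#' sentence, grouped by window length (all unigrams first, then bigrams,
#' ...), left to right within each length. Windows never cross sentence
#' boundaries. A medical concept is frequently a compound word, which is why
#' multi-token windows are candidates at all.
#'
#' @param sentence A sentence data.frame from [read_document()] (columns
#'   `surface`, `lemma`, `pos`, `line`, `tok`), or a plain character vector
#'   of tokens.
#' @param n_max Maximum window length (default 4).
#' @return A list of candidate phrases; each is a list with `tokens`,
#'   `lemmas`, `pos_tags`, `n`, `line`, `start`, `end`, `normalized`.
#' @export
generate_ngrams <- function(sentence, n_max = 4L) {
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1)
    stop("`n_max` must be a single integer >= 1")
  n_max <- as.integer(n_max)
  if (is.character(sentence)) {
    pos <- pos_tag_tokens(sentence)
    sentence <- data.frame(surface = sentence,
                           lemma = lemmatize_tokens(sentence, pos),
                           pos = pos, line = 1L,
                           tok = seq_along(sentence) - 1L,
                           stringsAsFactors = FALSE)
  }
  L <- nrow(sentence)
  out <- list()
  for (n in seq_len(n_max)) {
    if (n > L) break
    for (from in seq_len(L - n + 1L)) {
      out[[length(out) + 1L]] <- .make_candidate(sentence, from, from + n - 1L)
    }
  }
  out
}

#' Candidate phrases for a whole document
#'
#' Runs [generate_ngrams()] over every sentence and concatenates the
#' results in document order.
#'
#' @param doc A `clin_document`.
#' @param n_max Maximum n-gram length.
#' @return A list of candidate phrases.
#' @export
candidate_phrases <- function(doc, n_max = 4L) {
  stopifnot(inherits(doc, "clin_document"))
  unlist(lapply(doc$sentences, generate_ngrams, n_max = n_max),
         recursive = FALSE)
}

#' Drop duplicate candidate phrases
#'
#' Keeps the first occurrence of each normalized form; relative order is
#' preserved because downstream vote tie-breaking is positional.
#' Idempotent.
#'
#' @param phrases List of candidate phrases.
#' @return List of unique candidate phrases, original order.
#' @export
deduplicate_phrases <- function(phrases) {
  if (length(phrases) == 0L) return(phrases)
  norms <- vapply(phrases, function(p) p$normalized, character(1))
  phrases[!duplicated(norms)]
}

#' Filter a tagged token sequence to the content-word bag
#'
#' Retains only tokens whose Penn Treebank tag matches `NN*`, `JJ*` or
#' `RB*` — the regular-expression bag-of-words filter applied to single
#' tokens. Stopwords are also removed from this unigram bag.
#'
#' @param tokens Character vector of surface tokens.
#' @param pos_tags Matching Penn Treebank tags (tagged internally when
#'   omitted).
#' @param stopwords Stopword list (default the shipped list); set to
#'   `character(0)` to keep stopwords.
#' @return Character vector: the retained tokens, order preserved.
#' @export
pos_filter_bag <- function(tokens, pos_tags = NULL,
                           stopwords = clin_stopwords()) {
  if (length(tokens) == 0L) return(character(0))
  if (is.null(pos_tags)) pos_tags <- pos_tag_tokens(tokens)
  stopifnot(length(pos_tags) == length(tokens))
  keep <- grepl("^(NN|JJ|RB)", pos_tags) & !(tolower(tokens) %in% stopwords)
  tokens[keep]
}

# a token disqualifies (collects into the boundary algorithm's wordSet)
# when it is a stopword or tagged verb/adjective/adverb
.is_disqualified <- function(tokens, pos_tags, stopwords) {
  tolower(tokens) %in% stopwords |
    coarse_pos_class(pos_tags) %in% c("Verb", "Adjective", "Adverb")
}

#' Word-boundary identification over candidate phrases
#'
#' A candidate is retained if and only if at least one of its tokens is a
#' content token, i.e. not a stopword and not tagged verb, adjective or
#' adverb. Phrases made entirely of function words and modifiers ("is the",
#' "very good effect") are discarded; phrases that mix stopwords with
#' content words ("a pelvic fracture", "burst of atrial") are kept, since
#' interior stopwords are part of many compound clinical concepts. This is
#' a pure filter: output is a subsequence of the input.
#'
#' @param candidates List of candidate phrases (from [generate_ngrams()] or
#'   [candidate_phrases()]).
#' @param stopwords Stopword list (default the shipped list).
#' @return The retained candidates, input order preserved.
#' @export
identify_word_boundaries <- function(candidates,
                                     stopwords = clin_stopwords()) {
  keep <- vapply(candidates, function(p) {
    !all(.is_disqualified(p$tokens, p$pos_tags, stopwords))
  }, logical(1))
  candidates[keep]
}
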