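test_that("tokenizer splits words and punctuation and preserves lines", {
  expect_identical(tokenize(""), list())
  expect_identical(tokenize("   \n \n"), list())

  sents <- tokenize("The patient has a pelvic fracture.")
  expect_length(sents, 1L)
  expect_identical(sents[[1]]$surface,
                   c("The", "patient", "has", "a", "pelvic", "fracture", "."))
  expect_identical(sents[[1]]$tok, 0:6)
  expect_identical(sents[[1]]$line, rep(1L, 7))

  two <- tokenize("Chest pain noted.\nGiven aspirin 81 mg.")
  expect_length(two, 2L)
  expect_identical(unique(two[[1]]$line), 1L)
  expect_identical(unique(two[[2]]$line), 2L)
  # token indices restart per physical line
  expect_identical(two[[2]]$tok[1], 0L)

  # sentence-final punctuation splits within a line, line index unchanged
  mid <- tokenize("Denies pain. Tolerating diet.")
  expect_length(mid, 2L)
  expect_identical(unique(mid[[2]]$line), 1L)
  expect_identical(mid[[2]]$tok[1], 3L)

  # abbreviation periods and unit slashes stay inside the token
  abbr <- tokenize("Take q.d. with 10 mg/dL max.")
  expect_true("q.d." %in% abbr[[1]]$surface)
  expect_true("mg/dL" %in% abbr[[1]]$surface)
})

test_that("lemmatizer handles inflections and falls back to lowercase", {
  expect_identical(lemmatize_tokens("caring"), "care")
  expect_identical(lemmatize_tokens("fracture"), "fracture")
  expect_identical(lemmatize_tokens("arteries"), "artery")
  expect_identical(lemmatize_tokens("fractures"), "fracture")
  expect_identical(lemmatize_tokens("stress"), "stress")  # not a plural
  # out-of-vocabulary token -> lowercased surface
  expect_identical(lemmatize_tokens("Zzyxmab"), "zzyxmab")
  toks <- c("The", "patient", "was", "caring", "for", "arteries")
  expect_length(lemmatize_tokens(toks), length(toks))
})

test_that("n-gram generation enumerates contiguous windows in order", {
  out <- generate_ngrams(c("a", "b", "c"), n_max = 2)
  expect_identical(vapply(out, `[[`, "", "normalized"),
                   c("a", "b", "c", "a b", "b c"))
  expect_identical(vapply(out, `[[`, 1L, "start"), c(0L, 1L, 2L, 0L, 1L))

  expect_length(generate_ngrams("a", n_max = 4), 1L)
  expect_length(generate_ngrams(letters[1:6], n_max = 4), 18L)  # 6+5+4+3
  expect_error(generate_ngrams(c("a"), n_max = 0), "n_max")

  # window count equals sum over n of max(0, L - n + 1)
  set.seed(11)
  for (L in sample(1:12, 6)) {
    toks <- replicate(L, paste(sample(letters, 3), collapse = ""))
    expected <- sum(pmax(0L, L - seq_len(4) + 1L))
    expect_length(generate_ngrams(toks, n_max = 4), expected)
  }
})

test_that("deduplication keeps first occurrence and is idempotent", {
  expect_identical(deduplicate_phrases(list()), list())
  ph <- lapply(c("stress", "pain", "stress"), make_candidate)
  out <- deduplicate_phrases(ph)
  expect_identical(vapply(out, `[[`, "", "normalized"), c("stress", "pain"))
  expect_identical(deduplicate_phrases(out), out)
  # case variants collapse through normalization
  cv <- lapply(c("Stress", "stress"), make_candidate)
  expect_length(deduplicate_phrases(cv), 1L)
})

test_that("bag-of-words POS filter keeps noun/adjective/adverb tokens", {
  toks <- c("severe", "atherosclerosis", "was")
  tags <- c("JJ", "NN", "VBD")
  expect_identical(pos_filter_bag(toks, tags, stopwords = character(0)),
                   c("severe", "atherosclerosis"))
  expect_identical(pos_filter_bag(c("was", "went"), c("VBD", "VBD")),
                   character(0))
  # equals a brute-force regex over the tag string
  toks <- c("The", "very", "old", "man", "quickly", "denied", "chest",
            "pain", "and", "left")
  tags <- pos_tag_tokens(toks)
  oracle <- toks[grepl("^NN|^JJ|^RB", tags)]
  expect_identical(pos_filter_bag(toks, tags, stopwords = character(0)),
                   oracle)
  # the unigram bag additionally drops stopwords
  expect_false("very" %in% pos_filter_bag(toks, tags))
})

test_that("word-boundary filter keeps phrases with at least one content token", {
  keep_one <- function(p) length(identify_word_boundaries(list(p))) == 1L
  expect_false(keep_one(make_candidate("is the")))
  expect_false(keep_one(make_candidate("did have of")))
  expect_true(keep_one(make_candidate("a pelvic fracture")))
  expect_true(keep_one(make_candidate("burst of atrial")))
  expect_true(keep_one(make_candidate("have burst")))
  # retained by the boundary algorithm ("atrial" is a content noun), even
  # though a purely prose reading might discard it
  expect_true(keep_one(make_candidate("of atrial")))
  # "good effect" is retained: "effect" is a noun content token
  expect_true(keep_one(make_candidate("good effect")))
  expect_false(keep_one(make_candidate("very good")))
})

test_that("boundary filter equals the per-token oracle on fuzzed candidates", {
  sw <- clin_stopwords()
  pool <- c("the", "of", "was", "is", "a", "very", "good", "well", "did",
            "pelvic", "fracture", "heart", "rate", "stress", "atrial",
            "burst", "severe", "quickly", "caring", "aspirin", ".", ",")
  set.seed(42)
  cands <- replicate(1000, {
    make_candidate(paste(sample(pool, sample(1:4, 1), replace = TRUE),
                         collapse = " "))
  }, simplify = FALSE)
  kept <- identify_word_boundaries(cands, sw)
  oracle_keep <- vapply(cands, function(p) {
    any(vapply(seq_along(p$tokens), function(i) {
      tok <- tolower(p$tokens[i])
      cls <- coarse_pos_class(p$pos_tags[i])
      !(tok %in% sw || cls %in% c("Verb", "Adjective", "Adverb"))
    }, logical(1)))
  }, logical(1))
  expect_identical(vapply(kept, `[[`, "", "normalized"),
                   vapply(cands[oracle_keep], `[[`, "", "normalized"))
  # pure filter: output is a subsequence of the input
  expect_true(all(vapply(kept, `[[`, "", "normalized") %in%
                  vapply(cands, `[[`, "", "normalized")))
  # every retained candidate has a content token
  expect_true(all(oracle_keep[match(
    vapply(kept, function(p) paste(p$tokens, collapse = "\r"), ""),
    vapply(cands, function(p) paste(p$tokens, collapse = "\r"), ""))]))
})
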