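test_that("fixture KB answers the reference lookups byte-exactly", {
  cad <- search_concepts(kb, "coronary artery disease")
  expect_identical(cad$cui[1], "C0010054")
  expect_identical(cad$name[1], "Coronary Arteriosclerosis")

  trout <- search_concepts(kb, "trout")
  expect_identical(trout$cui, "C0041200")
  expect_identical(trout$name, "Salmo trutta")
  sty <- search_semantic_types(kb, "C0041200")
  expect_identical(sty$tui, "T013")
  expect_identical(sty$name, "Fish")
  et <- search_entity_type(kb, "T013")
  expect_identical(et$abbreviation, "LIVB")
  expect_identical(et$expanded_form, "Living Beings")
})

test_that("term lookups follow the backend contract", {
  expect_identical(nrow(search_concepts(kb, "zzzz-nonterm")), 0L)
  expect_error(search_concepts(kb, ""), "nzchar")
  expect_error(search_concepts(kb, "stress", limit = 0), "limit")

  # "stress" divides into four concepts, one of which carries two types
  stress <- search_concepts(kb, "stress")
  expect_identical(nrow(stress), 4L)
  bismuth <- stress$cui[stress$name == "Stress bismuth subsalicylate"]
  bsty <- search_semantic_types(kb, bismuth)
  expect_identical(nrow(bsty), 2L)
  expect_setequal(tolower(bsty$name),
                  c("organic chemical", "pharmacologic substance"))

  # unknown CUI -> empty, not an error; unknown TUI -> sentinel
  expect_identical(nrow(search_semantic_types(kb, "C9999999")), 0L)
  expect_identical(search_entity_type(kb, "T99999")$abbreviation, "UNKNOWN")

  # every concept carries 1..5 types, every fixture TUI resolves
  for (term in kb_terms(kb)) {
    for (cui in search_concepts(kb, term, limit = 100)$cui) {
      sty <- search_semantic_types(kb, cui)
      expect_true(nrow(sty) >= 1L && nrow(sty) <= 5L)
      for (tui in sty$tui) {
        expect_false(search_entity_type(kb, tui)$abbreviation == "UNKNOWN")
      }
    }
  }

  # search_concepts(term, k) is a prefix of search_concepts(term, k+1)
  for (k in 1:4) {
    a <- search_concepts(kb, "heart rate", limit = k)
    b <- search_concepts(kb, "heart rate", limit = k + 1)
    expect_identical(a, b[seq_len(nrow(a)), , drop = FALSE])
  }
  expect_identical(nrow(search_concepts(kb, "stress", limit = 1)), 1L)

  # determinism on a fixed snapshot
  q <- function() serialize(list(
    search_concepts(kb, "stress"),
    search_semantic_types(kb, "C0038435"),
    approximate_candidates(kb, "coronry artery disease", 0.6)),
    connection = NULL)
  expect_identical(q(), q())
})

test_that("approximate matching is trigram Jaccard with threshold semantics", {
  # identity scores 1.0 and comes first at any threshold
  out <- approximate_candidates(kb, "aspirin", 1.0)
  expect_identical(out$matched_term[1], "aspirin")
  expect_equal(out$score[1], 1.0)
  expect_identical(nrow(out), 1L)  # threshold 1.0 -> only the exact string

  # hand-computed trigram-Jaccard oracle, written independently
  oracle_sim <- function(a, b) {
    grams <- function(s) {
      s <- tolower(s)
      if (nchar(s) < 3) return(s)
      out <- character(0)
      for (i in 1:(nchar(s) - 2)) out <- c(out, substr(s, i, i + 2))
      unique(out)
    }
    ga <- grams(a); gb <- grams(b)
    length(intersect(ga, gb)) / length(union(ga, gb))
  }
  typo <- "coronry artery disease"
  out <- approximate_candidates(kb, typo, 0.7)
  expect_true("coronary artery disease" %in% out$matched_term)
  expect_equal(out$score[out$matched_term == "coronary artery disease"],
               oracle_sim(typo, "coronary artery disease"))
  expect_equal(trigram_similarity("heart", "rate"),
               oracle_sim("heart", "rate"))
  # symmetry
  expect_equal(trigram_similarity("stress", "strss"),
               trigram_similarity("strss", "stress"))

  # raising the threshold never adds candidates
  lower <- approximate_candidates(kb, typo, 0.6)$matched_term
  for (th in c(0.7, 0.8, 0.9, 1.0)) {
    expect_true(all(approximate_candidates(kb, typo, th)$matched_term
                    %in% lower))
  }

  expect_error(approximate_candidates(kb, "x", 0.5), "threshold")
  expect_error(approximate_candidates(kb, "x", 1.2), "threshold")
})

test_that("hybrid matching unions exact hits with approximate rescues", {
  m <- hybrid_match(kb, c("beta blockers", "coronry artery disease", "qqqq"),
                    threshold = 0.7)
  expect_identical(m[["beta blockers"]]$mode, "exact")
  expect_equal(m[["beta blockers"]]$score, 1.0)
  expect_identical(m[["coronry artery disease"]]$mode, "approximate")
  expect_identical(m[["coronry artery disease"]]$matched_term,
                   "coronary artery disease")
  expect_true(m[["coronry artery disease"]]$score >= 0.7)
  expect_null(m[["qqqq"]])
  # an exact hit is exact at every threshold
  expect_identical(hybrid_match(kb, "aspirin", 1.0)[["aspirin"]]$mode,
                   "exact")
  # exact-only mode never rescues
  expect_null(hybrid_match(kb, "coronry artery disease",
                           threshold = NULL)[["coronry artery disease"]])
})

test_that("fixture loader validates the schema", {
  empty <- tempfile(fileext = ".json")
  writeLines('{"terms": [], "entity_types": []}', empty)
  ekb <- load_fixture_kb(empty)
  expect_identical(nrow(search_concepts(ekb, "anything")), 0L)
  expect_length(kb_terms(ekb), 0L)

  dup <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"terms": [{"term": "x", "concepts": [',
    '{"cui": "C1", "name": "a", "root_source": "S",',
    ' "semantic_types": [{"tui": "T1", "name": "Finding"}]},',
    '{"cui": "C1", "name": "b", "root_source": "S",',
    ' "semantic_types": [{"tui": "T1", "name": "Finding"}]}]}],',
    ' "entity_types": []}'), dup)
  expect_error(load_fixture_kb(dup), "duplicate cui C1")

  bad <- tempfile(fileext = ".json")
  writeLines(paste0(
    '{"terms": [{"term": "x", "concepts": [',
    '{"cui": "C2", "name": "a", "root_source": "S",',
    ' "semantic_types": []}]}], "entity_types": []}'), bad)
  expect_error(load_fixture_kb(bad), "1..5 semantic types")
})
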