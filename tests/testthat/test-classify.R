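# The three canonical vote scenarios: a clear majority (rule 1), a
# three-way tie (rule 2) and a two-way tie with out-of-dictionary entries
# (rule 3), using the published semantic-type breakdowns.

breakdown_rule1 <- c("Pharmacologic Substance", "Organic Chemical",
                     "Pathologic Function", "Organic Chemical",
                     "Clinical Attribute", "Injury or Poisoning",
                     "Pharmacologic Substance")
breakdown_rule2 <- c("Clinical Attribute", "Clinical Attribute", "Finding",
                     "Finding", "Medical Device", "Medical Device")
breakdown_rule3 <- c("Finding", "Finding", "Clinical Attribute",
                     "Clinical Attribute", "Finding", "Clinical Attribute",
                     "Finding", "Clinical Attribute", "NONE", "NONE")

test_that("semantic types map to domain labels through the dictionaries", {
  expect_identical(label_semantic_types(breakdown_rule1),
                   c("Treatment", "Treatment", "Problem", "Treatment",
                     "Test", "Problem", "Treatment"))
  expect_identical(label_semantic_types(breakdown_rule2),
                   c("Test", "Test", "Problem", "Problem", "Treatment",
                     "Treatment"))
  expect_identical(label_semantic_types(breakdown_rule3),
                   c("Problem", "Problem", "Test", "Test", "Problem",
                     "Test", "Problem", "Test", "NONE", "NONE"))
  expect_identical(label_semantic_types("Some unknown type"), "NONE")
  # matching is case-insensitive
  expect_identical(label_semantic_types(c("DIAGNOSTIC PROCEDURE",
                                          "finding")),
                   c("Test", "Problem"))
})

test_that("the three dictionaries are pairwise disjoint", {
  d <- semantic_dictionaries()
  expect_length(d$problem, 12L)
  expect_length(d$treatment, 9L)
  expect_length(d$test, 7L)
  expect_identical(anyDuplicated(tolower(unlist(d))), 0L)
})

test_that("majority vote reproduces the three worked scenarios", {
  v1 <- majority_vote(label_semantic_types(breakdown_rule1))
  expect_identical(v1$winner, "Treatment")
  expect_identical(unname(v1$counts[c("Treatment", "Problem", "Test")]),
                   c(4L, 2L, 1L))
  expect_identical(v1$rule_applied, "rule1")

  v2 <- majority_vote(label_semantic_types(breakdown_rule2))
  expect_identical(v2$winner, "Test")
  expect_identical(unname(v2$counts), c(2L, 2L, 2L))
  expect_identical(v2$rule_applied, "rule2")

  v3 <- majority_vote(label_semantic_types(breakdown_rule3))
  expect_identical(v3$winner, "Problem")
  expect_identical(unname(v3$counts[c("Problem", "Test", "Treatment")]),
                   c(4L, 4L, 0L))
  expect_identical(v3$rule_applied, "rule3")

  v0 <- majority_vote(character(0))
  expect_identical(v0$rule_applied, "unclassified")
  expect_true(is.na(v0$winner))
  expect_identical(majority_vote(c("NONE", "NONE"))$rule_applied,
                   "unclassified")
  expect_error(majority_vote(c("Problem", "Bogus")), "labels")
})

test_that("majority vote equals the brute-force oracle exhaustively", {
  symbols <- c("Problem", "Treatment", "Test", "NONE")
  for (len in 0:6) {
    grid <- if (len == 0) matrix(character(0), nrow = 1)
            else as.matrix(expand.grid(rep(list(symbols), len),
                                       stringsAsFactors = FALSE))
    for (i in seq_len(nrow(grid))) {
      labels <- as.character(grid[i, ])
      v <- majority_vote(labels)
      expect_identical(v$winner, oracle_vote_winner(labels))
      # vote conservation
      expect_identical(sum(v$counts), sum(labels != "NONE"))
    }
  }
})

test_that("permuting labels preserves counts, and rule-1 winners", {
  set.seed(7)
  for (rep in 1:50) {
    labels <- sample(c("Problem", "Treatment", "Test", "NONE"),
                     sample(1:8, 1), replace = TRUE)
    v <- majority_vote(labels)
    perm <- sample(labels)
    vp <- majority_vote(perm)
    expect_identical(v$counts, vp$counts)
    if (v$rule_applied == "rule1") expect_identical(vp$winner, v$winner)
  }
})

test_that("classify_term assigns the fixture terms their categories", {
  ann_for <- function(term) {
    rec <- extract_semantics(list(make_candidate(term)), kb)[[1]]
    classify_term(rec)
  }
  expect_identical(ann_for("beta blockers")$category, "treatment")
  expect_identical(ann_for("heart rate")$category, "test")
  expect_identical(ann_for("increased heart rate")$category, "problem")
  expect_identical(ann_for("coronary artery disease")$category, "problem")
  expect_identical(ann_for("coronary artery disease")$vote$counts[["Problem"]], 3L)
  # a term whose types are all outside the dictionaries yields nothing
  expect_null(ann_for("trout"))
})

test_that("the pipeline annotates notes end to end", {
  anns <- run_pipeline("The patient was started on beta blockers today .",
                       kb)
  expect_length(anns, 1L)
  expect_identical(anns[[1]]$category, "treatment")
  expect_identical(anns[[1]]$text, "beta blockers")

  expect_identical(run_pipeline("", kb), list())
  expect_identical(run_pipeline("she was very well today .", kb), list())

  # nested spans resolve to the longest match
  anns <- run_pipeline("He has increased heart rate now .", kb)
  expect_length(anns, 1L)
  expect_identical(anns[[1]]$text, "increased heart rate")
  expect_identical(anns[[1]]$category, "problem")
  expect_identical(c(anns[[1]]$start, anns[[1]]$end), c(2L, 4L))

  # deterministic: identical runs serialize identically
  note <- "She was given aspirin for chest pain .\nHeart rate was stable ."
  a <- serialize(run_pipeline(note, kb), connection = NULL)
  b <- serialize(run_pipeline(note, kb), connection = NULL)
  expect_identical(a, b)
})

test_that("exact matches outrank approximate matches in overlap resolution", {
  # "for pelvic fracture" approx-matches "pelvic fracture" as a longer
  # span; the exact nested hit must win
  anns <- run_pipeline("He came in for pelvic fracture today .", kb)
  expect_length(anns, 1L)
  expect_identical(anns[[1]]$text, "pelvic fracture")
  expect_identical(anns[[1]]$match$mode, "exact")
})
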