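---
title: "Rule-based clinical concept extraction and classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based clinical concept extraction and classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinconcept)
```

This vignette documents the model behind `clinconcept`, the design
choices that were genuinely open, the tunable parameters, what the
synthetic test world does and does not show, and the package's known
limitations.

## The extraction model

The pipeline treats concept extraction as dictionary lookup over
carefully chosen candidate spans, not as sequence labeling. For a note
$D$ with words $W = \{w_1, \dots, w_n\}$:

1. **Tokenization and tagging.** Notes are line-oriented; both a newline
   and sentence-final punctuation end a sentence, but annotation offsets
   stay (line, token-within-line), 1-based lines and 0-based tokens, the
   i2b2 convention. Punctuation is peeled off word edges into its own
   tokens; abbreviation-internal periods (`q.d.`) and unit slashes
   (`mg/dL`) stay inside the token — clinical punctuation handling has
   no single standard, and this choice keeps dose expressions intact
   while still splitting sentence punctuation.
2. **Candidates.** All contiguous n-grams with $n \le n_{max}$
   (default 4) within a sentence. Four is enough for most compound
   clinical concepts ("overall left ventricular systolic function");
   longer spans trade recall of rare composites for a quadratic growth
   in lookups.
3. **Boundary filtering.** A token is *disqualifying* when it is a
   stopword or tagged verb/adjective/adverb; a candidate is retained iff
   at least one token is *not* disqualifying. The rule deliberately
   keeps mixed phrases ("a pelvic fracture", "burst of atrial"): interior
   stopwords are part of many compound concepts. Note the asymmetry with
   the unigram bag-of-words filter (`pos_filter_bag()`), which *keeps*
   adjectives and adverbs (`NN*|JJ*|RB*`): a lone adjective can carry
   meaning in a bag-of-words view, but contributes no concept boundary
   on its own. Where a prose description of such filtering might drop
   "good effect", the boundary algorithm retains it ("effect" is a
   noun); we implement the algorithmic rule and note the discrepancy
   here rather than in code.
4. **Duplicate removal** keeps the first occurrence of each normalized
   form (lowercased, edge punctuation stripped, whitespace collapsed).
   Order preservation matters: tie-breaking downstream is positional.

### Tagging and lemmatization

No statistical tagger is trained or loaded. The tagger is a closed-class
lexicon (determiners, prepositions, pronouns, auxiliaries, common
clinical verbs/adjectives/adverbs) plus suffix rules, defaulting to
noun. The default matters: boundary filtering only needs to recognize
*non*-content tokens, and an unknown token in a clinical note is far
more likely a medical noun than anything else, so the noun default is
the conservative choice for candidate retention. The lemmatizer is a
small irregular-form table plus POS-aware suffix detachment (verbal
`-ing`/`-ed` with stem restoration, nominal plurals including common
Latin/Greek medical plurals), falling back to the lowercased surface.
Both are deterministic, so the whole pipeline is reproducible
byte-for-byte.

Lemmatization happens once, at tokenization; candidates carry both
surface and lemma forms, and lookup tries the surface phrase first,
then the lemma phrase. Surface-first means an exactly listed inflected
term ("beta blockers") matches the terminology entry as written rather
than a lemmatized variant.

## Terminology lookup

A knowledge backend answers three queries — term → concepts (with CUI,
preferred name, source vocabulary), CUI → 1–5 semantic types (TUI,
name), TUI → one semantic group — plus approximate matching over its
term inventory. Two implementations share the contract: an offline JSON
fixture (the default; see below) and an optional client for a UTS-style
terminology REST service, which needs network access and an API key and
is therefore exercised by no test.

* **Concept cap.** Only the first `concept_limit` concepts (default 8)
  of a term enter the breakdown, in the backend's preference order.
  Retrieval accuracy on annotated clinical corpora plateaus around
  eight concepts; fewer under-represents ambiguous terms, more adds
  noise from rare senses.
* **Approximate matching.** Similarity is the Jaccard index over sets
  of character trigrams of the lowercased strings — deterministic,
  symmetric, order-free, and standard for dictionary matching. The
  threshold is confined to $[0.6, 1.0]$, the range in which approximate
  concept matching is usefully selective; default 0.7. A useful
  calibration: one mid-word character substitution in a phrase with $g$
  trigrams leaves similarity $\approx (g-3)/(g+3)$, so 0.7 tolerates
  typos only in phrases of roughly 20+ characters while 0.6 reaches
  down to ~14 characters. Each candidate phrase is matched
  independently against the inventory.
* **Hybrid matching.** Exact lookup first; approximate only for the
  remainder; union of both. Exact-only misses inflected and misspelled
  mentions; approximate-only sacrifices precision; the hybrid is the
  package default.

## Classification by majority vote

Three disjoint semantic-type dictionaries define the domains: 12
problem types ("Disease or Syndrome" … "virus/bacterium"), 9 treatment
types ("Therapeutic or Preventive Procedure" … "Medical Device"), 7
test types ("Tissue" … "Body Substance"). Matching is case-insensitive
exact string match; the dictionaries are user-overridable for domain
extension. Each semantic type in a term's flattened breakdown (concept
order, then within-concept order) contributes one label; names in no
dictionary contribute `NONE`, which is removed before counting.

The category is $T \leftarrow \arg\max_i C_i$ over the label counts,
with three rules:

* **Rule 1** — a unique maximum wins.
* **Rule 2** — a three-way tie goes to the class whose label occurs
  earliest in the breakdown sequence.
* **Rule 3** — a two-way tie above the third class goes to whichever of
  the two tied classes occurs earliest.

The tie-break is *positional*, not a fixed class priority. Both
canonical tie scenarios resolve this way: "heart rate"
(`Test, Test, Problem, Problem, Treatment, Treatment` — 2-2-2) goes to
Test because Test occurs first, and "increased heart rate" (4-4-0
after dropping two NONEs) goes to Problem because Problem occurs first.
A fixed-order reading ("Problem beats Treatment beats Test") would
give the same result for the second scenario but the wrong one for the
first; we therefore implement the positional reading. Since concept
order is the backend's preference order, the earliest label comes from
the most preferred sense — a sensible prior when the vote itself cannot
decide. Entity types (semantic groups) are carried as metadata only;
classification operates at semantic-type level, where the dictionaries
are defined.

### Overlap resolution

Nested and overlapping classified spans are resolved by ranking: exact
matches before approximate, then higher similarity score, then longer
span, then leftmost, keeping greedily by rank. Longer-before-shorter
reflects that composite terms are more meaningful than their parts
("increased heart rate" over "heart rate"). Mode and score come first
because approximate matching at permissive thresholds will happily
match a phrase *plus an adjacent function word* ("have coronary artery
disease" ~ the three-word term at similarity ≥ 0.6): without the
preference, the sloppier longer span would displace the tight one.
Among exact matches all scores are 1, so the longest-span rule is
unchanged there. Spans with punctuation-only edge tokens are excluded
up front — a trailing-period 4-gram normalizes to the same lookup form
as the clean 3-gram and would otherwise inflate the reported span.

## Evaluation

Span scoring is one-to-one greedy left-to-right matching; `exact`
(same line, same token range, same category) is the default, `overlap`
(any token overlap, same category) is available — both protocols are
reported in the NER literature and exact is the stricter. Per-class
TP/FP/FN give precision, recall and F1 (with the 0-denominator
conventions), macro averages follow
$fP = \frac{1}{N}\sum TP_i/TI_i$, $fR = \frac{1}{N}\sum TP_i/TT_i$,
$fF$ their harmonic mean, where $TI$/$TT$ are inferred and ground-truth
label totals; a class with a zero denominator contributes 0 and is
reported. Boundary sensitivity is $TP/(TP+FN)$ over gold spans
surviving boundary detection; we count concept spans, not documents.
Reports render percentages rounded half-up to two decimals.

## The synthetic test world

Licensed resources (the full UMLS Metathesaurus, the i2b2-2010
corpora) cannot be redistributed, so the package generates its own test
world:

* **Fixture knowledge base** (`build_fixture_kb()`): ~12 terms,
  36 concepts. It reproduces the reference lookups byte-exactly
  (C0010054 "Coronary Arteriosclerosis"; C0041200 "Salmo trutta" /
  T013 "Fish" / "Living Beings"; "stress" with four concepts including
  a two-type concept) and encodes the three canonical vote breakdowns
  verbatim as flattened semantic-type sequences. The ten-entry
  breakdown of "increased heart rate" exceeds eight single-type
  concepts, so its eighth concept carries three types (Clinical
  Attribute, NONE, NONE), keeping the verbatim sequence within the
  eight-concept cap. CUIs/TUIs beyond the published ones are synthetic
  but UMLS-shaped.
* **Synthetic corpora** (`generate_synthetic_corpus()`): seeded,
  byte-reproducible notes, one planted vocabulary phrase per line
  between distractor fragments drawn from a stopword/verb/adverb-heavy
  template pool. Distractor-only n-grams are entirely removed by
  boundary filtering, and mixed n-grams always overlap a planted span,
  so by construction the pipeline recovers the planted corpus with
  precision = recall = 1 — the end-to-end smoke test. Gold categories
  are *derived* by running the vote against the knowledge base at
  generation time, never hardcoded, so KB and gold cannot drift apart.
  An optional typo injector (single-character substitutions) exercises
  approximate matching with a known oracle; optional category weights
  produce class-imbalanced corpora.

What passing these tests does **not** show: real discharge summaries
have section headers, tables, nonstandard abbreviations, negation and
misspelled distractor text that *does* resemble terminology entries;
the synthetic world has none of these, so perfect synthetic scores say
the machinery is correct, not that real-corpus scores would be high.
Test-suite problem sizes — a 12-term knowledge base, corpora of 2–5
notes with 3–8 planted concepts, 1000-candidate boundary fuzzing, and
the exhaustive vote-oracle sweep over all $4^0..4^6$ label sequences —
were chosen as the smallest sizes that exercise every rule and
tie-break.

## Numerical and degenerate-input conventions

* Empty text, empty phrase lists, empty knowledge bases and empty label
  sequences all flow through as empty results, never errors; an
  all-`NONE` term is simply unclassified.
* Unknown CUI → empty type list; unknown TUI → sentinel
  `("UNKNOWN", "Unknown")`; both distinct from I/O failure, which (for
  the remote backend) raises a retryable `kb_io_error`.
* A concept with no semantic types is dropped with a warning rather
  than failing the pipeline; a term left with no concepts drops out.
* Approximate-candidate ties at equal score are ordered
  lexicographically, so results are stable across platforms.
* The threshold range check rejects values outside $[0.6, 1.0]$;
  `n_max < 1` and negative counts are invalid-parameter errors.

## Limitations

* No negation or assertion detection: "denies chest pain" yields a
  *problem* annotation for "chest pain".
* No abbreviation expansion; "MI" matches only if the terminology lists
  it.
* The heuristic tagger and lemmatizer trade coverage for
  reproducibility; genuinely ambiguous tokens (e.g. "left" as verb vs
  laterality) default toward the reading that retains candidates.
* Strict word boundaries struggle with compound constructions such as
  "saphenous vein graft -> posterior descending artery", a known hard
  case for rule-based boundary detection.
* The remote terminology client is functional but unexercised by the
  test suite; the fixture backend is the tested reference.
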