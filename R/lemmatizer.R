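# Lightweight morphological lemmatizer: a small irregular-form table plus
# suffix-detachment rules in the style of WordNet's morphy, selected by the
# coarse POS class of each token. Out-of-vocabulary tokens fall back to the
# lowercased surface form.

.irregular_lemmas <- c(
  # verbs
  was = "be", were = "be", is = "be", are = "be", am = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have", does = "do",
  did = "do", done = "do", went = "go", gone = "go", saw = "see",
  seen = "see", took = "take", taken = "take", gave = "give",
  given = "give", made = "make", came = "come", got = "get", felt = "feel",
  found = "find", kept = "keep", said = "say", underwent = "undergo",
  became = "become", began = "begin", lay = "lie",
  increased = "increase", decreased = "decrease",
  # -ing forms whose stem restoration is not rule-predictable
  singing = "sing", bringing = "bring", ringing = "ring",
  lying = "lie", dying = "die", tying = "tie",
  # nouns
  feet = "foot", teeth = "tooth", men = "man", women = "woman",
  children = "child", people = "person", mice = "mouse", lives = "life",
  diagnoses = "diagnosis", stenoses = "stenosis", prognoses = "prognosis",
  metastases = "metastasis", anastomoses = "anastomosis",
  emboli = "embolus", thrombi = "thrombus", fungi = "fungus",
  bacteria = "bacterium", criteria = "criterion", data = "datum",
  femora = "femur", viscera = "viscus", ganglia = "ganglion",
  vertebrae = "vertebra", bullae = "bulla"
)

# words that end in 's' but are singular (no plural detachment)
.s_final_singulars <- c(
  "diabetes", "herpes", "scabies", "rabies", "diuresis", "pertussis",
  "sepsis", "pelvis", "ascites", "series", "species", "news", "pancreas",
  "atherosclerosis", "arteriosclerosis", "stress", "abscess", "pus",
  "mucus", "lupus", "ileus", "bolus", "status", "tinnitus", "pruritus"
)

.lemma_one <- function(token, pos_class) {
  low <- tolower(token)
  irr <- .irregular_lemmas[low]
  if (!is.na(irr)) return(unname(irr))
  if (pos_class %in% c("Verb", "Adjective", "Adverb")) {
    if (nchar(low) > 4 && endsWith(low, "ing")) return(.restore_stem(substr(low, 1, nchar(low) - 3)))
    if (nchar(low) > 3 && endsWith(low, "ed"))  return(.restore_stem(substr(low, 1, nchar(low) - 2)))
  }
  if (pos_class %in% c("Noun", "Other") && !(low %in% .s_final_singulars)) {
    if (nchar(low) > 3 && endsWith(low, "ies")) return(paste0(substr(low, 1, nchar(low) - 3), "y"))
    if (nchar(low) > 4 && grepl("(ches|shes|sses|xes|zes)$", low)) return(substr(low, 1, nchar(low) - 2))
    if (nchar(low) > 2 && endsWith(low, "s") && !grepl("(ss|us|is)$", low)) return(substr(low, 1, nchar(low) - 1))
  }
  low
}

# after stripping -ing/-ed: undouble a doubled final consonant
# ("stopp" -> "stop") or restore a dropped silent e after a
# consonant-vowel-consonant stem ("car" -> "care", "mak" -> "make")
.restore_stem <- function(stem) {
  n <- nchar(stem)
  last <- substr(stem, n, n)
  prev <- if (n > 1) substr(stem, n - 1, n - 1) else ""
  vowels <- c("a", "e", "i", "o", "u")
  if (n > 2 && last == prev && !(last %in% vowels)) return(substr(stem, 1, n - 1))
  prev2 <- if (n > 2) substr(stem, n - 2, n - 2) else ""
  if (n > 2 && !(last %in% c(vowels, "w", "x", "y")) && prev %in% vowels && !(prev2 %in% vowels)) {
    return(paste0(stem, "e"))
  }
  stem
}

#' Lemmatize surface tokens
#'
#' Returns one lemma per token using a small irregular-form table and
#' POS-aware suffix-detachment rules (verbal `-ing`/`-ed` with stem
#' restoration, nominal plural endings). A token the rules do not cover is
#' returned as its lowercased surface form.
#'
#' @param tokens Character vector of surface tokens (nonempty strings).
#' @param pos_tags Optional character vector of Penn Treebank tags of the
#'   same length; when omitted the tokens are tagged with
#'   [pos_tag_tokens()].
#' @return Character vector of lemmas, same length as `tokens`.
#' @examples
#' lemmatize_tokens(c("caring", "arteries", "fracture"))
#' @export
lemmatize_tokens <- function(tokens, pos_tags = NULL) {
  if (length(tokens) == 0L) return(character(0))
  stopifnot(is.character(tokens), all(nzchar(tokens)))
  if (is.null(pos_tags)) pos_tags <- pos_tag_tokens(tokens)
  stopifnot(length(pos_tags) == length(tokens))
  classes <- coarse_pos_class(pos_tags)
  mapply(.lemma_one, tokens, classes, USE.NAMES = FALSE)
}
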