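# Lexicon-and-suffix part-of-speech tagger producing Penn Treebank tags.
#
# The extraction pipeline only consumes the coarse distinction
# noun / verb / adjective / adverb / function-word, so the tagger is a
# closed-class lexicon plus suffix heuristics with a noun default: unknown
# tokens (the typical case for clinical vocabulary) are treated as content
# words, which is the conservative choice for candidate retention.

.tag_lexicon <- local({
  lex <- list(
    DT  = c("a", "an", "the", "this", "that", "these", "those", "each",
            "every", "some", "any", "no", "all", "both", "another"),
    IN  = c("of", "in", "on", "at", "by", "for", "with", "about", "against",
            "between", "into", "through", "during", "before", "after",
            "above", "below", "to", "from", "under", "over", "until",
            "while", "as", "than", "because", "if", "since", "without",
            "within", "upon", "per"),
    PRP = c("i", "me", "my", "we", "us", "our", "you", "your", "he", "him",
            "his", "she", "her", "it", "its", "they", "them", "their",
            "himself", "herself", "itself", "themselves"),
    CC  = c("and", "but", "or", "nor", "so", "yet"),
    MD  = c("can", "could", "may", "might", "must", "shall", "should",
            "will", "would"),
    VBD = c("was", "were", "did", "had", "said", "went", "got", "came",
            "took", "saw", "felt", "found", "gave", "kept", "made",
            "became", "began", "underwent", "denied", "reported",
            "presented", "received", "showed", "revealed", "noted",
            "complained", "admitted", "discharged", "started", "stopped",
            "continued", "improved", "resolved", "tolerated", "developed",
            "experienced", "appeared", "remained", "returned", "walked"),
    VBZ = c("is", "has", "does", "says", "goes", "gets", "takes", "feels",
            "shows", "reveals", "denies", "reports", "presents",
            "receives", "remains", "appears", "complains", "continues"),
    VBP = c("am", "are", "have", "do", "take", "feel", "show", "deny",
            "report", "present", "receive", "remain", "appear", "complain",
            "continue", "go", "get", "say"),
    VB  = c("be", "give", "keep", "make", "see", "come", "start", "stop",
            "follow", "return", "monitor", "avoid", "rest", "eat", "drink",
            "call"),
    VBN = c("been", "done", "given", "taken", "seen", "known", "shown",
            "prescribed", "administered", "performed", "obtained",
            "ordered", "scheduled", "advised", "observed", "managed",
            "treated"),
    RB  = c("not", "n't", "very", "too", "quite", "rather", "well", "also",
            "again", "then", "here", "there", "now", "never", "always",
            "often", "sometimes", "still", "just", "only", "further",
            "once", "twice", "however", "perhaps", "approximately", "away",
            "home", "yesterday", "today", "tomorrow", "overnight"),
    JJ  = c("good", "bad", "mild", "severe", "acute", "chronic", "stable",
            "normal", "abnormal", "elevated", "high", "low", "large",
            "small", "new", "old", "left", "right", "bilateral", "afebrile",
            "alert", "awake", "comfortable", "fine", "healthy", "intact",
            "nontender", "other", "same", "several", "significant",
            "unremarkable", "well-nourished", "extensive", "moderate",
            "minimal", "diffuse", "focal", "patent", "prior", "recent",
            "multiple", "early", "late", "daily", "oral", "overall"),
    WDT = c("which", "what"),
    WP  = c("who", "whom"),
    WRB = c("when", "where", "why", "how"),
    EX  = c("there")
  )
  tags <- rep(names(lex), lengths(lex))
  words <- unlist(lex, use.names = FALSE)
  # first listing wins where a word appears under two tags
  keep <- !duplicated(words)
  stats::setNames(tags[keep], words[keep])
})

#' Tag tokens with Penn Treebank part-of-speech tags
#'
#' A deterministic lexicon plus suffix-rule tagger. Closed-class words
#' (determiners, prepositions, pronouns, auxiliaries, ...) come from a fixed
#' lexicon; remaining tokens are tagged by suffix (`-ly` adverb, `-ing` /
#' `-ed` verb forms, common adjectival endings) and default to noun, the
#' dominant class in clinical vocabulary.
#'
#' @param tokens Character vector of surface tokens.
#' @return Character vector of Penn Treebank tags, same length as `tokens`.
#' @examples
#' pos_tag_tokens(c("The", "patient", "has", "a", "pelvic", "fracture", "."))
#' @export
pos_tag_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  vapply(tokens, .tag_one_token, character(1), USE.NAMES = FALSE)
}

.tag_one_token <- function(tok) {
  low <- tolower(tok)
  if (grepl("^[[:punct:]]+$", tok)) {
    return(switch(tok, "," = ",", "." = ".", ":" = ":", ";" = ":",
                  "(" = "-LRB-", ")" = "-RRB-", "``"))
  }
  if (grepl("^[0-9]+([.,/:-][0-9]+)*%?$", tok)) return("CD")
  hit <- .tag_lexicon[low]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(low)
  if (n > 3 && endsWith(low, "ly")) return("RB")
  if (n > 4 && endsWith(low, "ing")) return("VBG")
  if (n > 3 && endsWith(low, "ed")) return("VBN")
  if (n > 4 && grepl("(ous|ful|ive|able|ible|ical|less|ish)$", low)) return("JJ")
  if (n > 3 && grepl("(er|est)$", low) && grepl("^(bigg|small|larg|great|few|weak|strong|old|young|high|low|wid|narrow)", low)) {
    return(if (endsWith(low, "est")) "JJS" else "JJR")
  }
  if (grepl("s$", low) && !grepl("(ss|us|is)$", low)) return("NNS")
  if (grepl("^[A-Z]", tok) && low != tok) "NNP" else "NN"
}

#' Coarse word class of a Penn Treebank tag
#'
#' Maps `VB*` to `"Verb"`, `JJ*` to `"Adjective"`, `RB*` to `"Adverb"`,
#' `NN*` to `"Noun"`; everything else (function words, punctuation,
#' numerals) to `"Other"`.
#'
#' @param tags Character vector of Penn Treebank tags.
#' @return Character vector of coarse classes.
#' @export
coarse_pos_class <- function(tags) {
  out <- rep("Other", length(tags))
  out[startsWith(tags, "VB") | tags == "MD"] <- "Verb"
  out[startsWith(tags, "JJ")] <- "Adjective"
  out[startsWith(tags, "RB") | tags %in% c("WRB")] <- "Adverb"
  out[startsWith(tags, "NN")] <- "Noun"
  out
}
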