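#' Default stylistic marker lexicons
#'
#' Eight function-word categories commonly used for linguistic style
#' coordination: articles, auxiliary verbs, conjunctions, high-frequency
#' adverbs, indefinite pronouns, personal pronouns, prepositions, and
#' quantifiers. These are open word lists (the widely used proprietary
#' category dictionaries are licensed and are not shipped); any lexicon of the
#' same shape can be substituted.
#'
#' @return Named list of character vectors (marker name -> word list).
#' @export
default_marker_lexicons <- function() {
  list(
    article = c("a", "an", "the"),
    auxverb = c("am", "is", "are", "was", "were", "be", "been", "being",
                "have", "has", "had", "do", "does", "did", "can", "could",
                "will", "would", "shall", "should", "may", "might", "must"),
    conj = c("and", "but", "or", "because", "so", "although", "while",
             "if", "then", "also"),
    adverb = c("very", "really", "just", "about", "too", "quite",
               "always", "never", "often", "again"),
    ipron = c("it", "its", "something", "anything", "nothing", "everything",
              "somebody", "anybody", "nobody", "everyone", "that", "this",
              "those", "these"),
    ppron = c("i", "me", "my", "mine", "you", "your", "yours", "he", "him",
              "his", "she", "her", "hers", "we", "us", "our", "they",
              "them", "their"),
    prep = c("in", "on", "at", "to", "of", "for", "with", "from", "by",
             "over", "under", "between", "into", "through", "after",
             "before", "during"),
    quant = c("all", "some", "many", "few", "much", "more", "most", "less",
              "least", "several", "each", "every", "both", "none"))
}

#' Default psycholinguistic category lexicons
#'
#' Open word lists for temporal orientation (past/present/future), self- vs
#' other-focus (first-person singular vs third-person pronouns), and
#' sentiment (positive/negative emotion). Entries may carry a trailing `*`
#' wildcard matching any suffix, in the style of stem-based category
#' dictionaries.
#'
#' @return Named list of character vectors.
#' @export
default_category_lexicons <- function() {
  list(
    past = c("was", "were", "had", "did", "been", "ago", "yesterday",
             "earlier", "used", "happened", "said", "told", "went",
             "felt", "lost"),
    present = c("is", "am", "are", "now", "today", "currently", "right",
                "being", "feel", "feels", "happening", "know", "think",
                "want", "need"),
    future = c("will", "going", "gonna", "tomorrow", "soon", "later",
               "future", "plan", "plans", "hope", "hopes", "might",
               "shall", "eventually", "forward"),
    first_singular = c("i", "me", "my", "mine", "myself", "im", "ive", "ill"),
    third_person = c("he", "him", "his", "she", "her", "hers", "they",
                     "them", "their", "theirs", "himself", "herself",
                     "themselves"),
    pos_emo = c("good", "great", "glad", "happy", "love", "loved", "nice",
                "better", "best", "calm", "relief", "relieved", "thank*",
                "appreciat*", "support*", "comfort*", "safe", "okay"),
    neg_emo = c("bad", "sad", "hurt", "hurts", "pain", "painful", "awful",
                "terrible", "hate", "worse", "worst", "scared", "afraid",
                "alone", "lonely", "angry", "anxious", "depress*", "cry*",
                "worthless", "hopeless"))
}

#' Default counselor response-class patterns
#'
#' Regular-expression patterns (matched case-insensitively against the raw
#' reply text) used to classify counselor responses into check questions,
#' suicide-ideation checks, thanks/affirmation, hedges, and surprise.
#' The surprise class additionally requires the message to open with an
#' interjection. All patterns are editable; these defaults cover the
#' standard exemplars of each class.
#'
#' @return Named list of character vectors of regex patterns.
#' @export
default_response_patterns <- function() {
  list(
    check_question = c("sounds like", "it seems", "i hear", "i understand",
                       "if i understand"),
    suicide_check = c("suicid", "kill (yourself|myself|themselves)",
                      "want(s)? to die", "end (my|your) life",
                      "hurt(ing)? (yourself|myself)"),
    thanks = c("thank", "appreciate", "courage", "brave",
               "glad you reached"),
    hedge = c("\\bmaybe\\b", "\\bperhaps\\b", "\\bfairly\\b",
              "\\bkind of\\b", "\\bsort of\\b", "\\ba little\\b",
              "\\bpossibly\\b", "\\bsomewhat\\b"),
    surprise = c("^\\W*(oh|wow|whoa)\\b"))
}

#' Single-token hedge word list
#'
#' Token-level counterpart of the hedge patterns, used where features are
#' computed over token lists rather than raw text.
#'
#' @return Character vector.
#' @export
default_hedge_words <- function() {
  c("maybe", "perhaps", "fairly", "possibly", "somewhat", "apparently")
}

#' Match tokens against a lexicon with trailing-wildcard support
#'
#' An entry ending in `*` matches any token beginning with the stem before
#' the `*`; other entries match exactly.
#'
#' @param tokens Character vector of tokens.
#' @param lexicon Character vector of lexicon entries.
#' @return Logical vector: which tokens hit the lexicon.
#' @export
lexicon_hits <- function(tokens, lexicon) {
  if (length(tokens) == 0) return(logical(0))
  wild <- endsWith(lexicon, "*")
  hit <- tokens %in% lexicon[!wild]
  for (stem in substr(lexicon[wild], 1L, nchar(lexicon[wild]) - 1L)) {
    hit <- hit | startsWith(tokens, stem)
  }
  hit
}

#' Read a lexicon file
#'
#' YAML mapping of class name to list of entries (words or patterns).
#'
#' @param path Path to a YAML file.
#' @return Named list of character vectors.
#' @export
read_lexicon <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read lexicon files")
  }
  lex <- yaml::read_yaml(path)
  lapply(lex, as.character)
}
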