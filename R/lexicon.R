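# Closed ~600-form lexicon with hand-assigned coarse POS and topic labels.
#
# The lexicon serves two purposes: it is the vocabulary of the synthetic
# corpus generator, and it backs the deterministic rule tagger and toy
# embedding backend, so every pipeline stage can be tested without a model
# download. Content categories (noun/verb/adjective/adverb) are split between
# two topics, "A" (self, home, everyday life — the interviewer's prompt
# domain) and "B" (work, machines, weather — the drift target). Function
# words are topic-neutral for sampling; for the toy embedder they are
# assigned alternately to A and B, which contributes a symmetric baseline
# offset to embedding distances (a nonzero trajectory intercept), mimicking
# how real sentence embeddings never coincide with the prompt embedding.

.inflect_noun <- function(stems) {
  plur <- ifelse(grepl("(s|sh|ch|x)$", stems), paste0(stems, "es"),
          ifelse(grepl("[^aeiou]y$", stems),
                 paste0(sub("y$", "", stems), "ies"),
                 paste0(stems, "s")))
  c(stems, plur)
}

.inflect_verb <- function(stems) {
  s3 <- ifelse(grepl("(s|sh|ch|x|o)$", stems), paste0(stems, "es"),
        ifelse(grepl("[^aeiou]y$", stems),
               paste0(sub("y$", "", stems), "ies"),
               paste0(stems, "s")))
  ed <- ifelse(grepl("e$", stems), paste0(stems, "d"),
        ifelse(grepl("[^aeiou]y$", stems),
               paste0(sub("y$", "", stems), "ied"),
               paste0(stems, "ed")))
  ing <- ifelse(grepl("[^eyo]e$", stems),
                paste0(sub("e$", "", stems), "ing"),
                paste0(stems, "ing"))
  c(stems, s3, ed, ing)
}

.lexicon_env <- new.env(parent = emptyenv())

#' The built-in closed lexicon
#'
#' @return data.frame with columns `word` (lower-case surface), `pos` (one of
#'   the ten coarse categories), `topic` (`"A"` or `"B"`) and
#'   `pronoun_class`.
#' @export
builtin_lexicon <- function() {
  if (!is.null(.lexicon_env$lexicon)) return(.lexicon_env$lexicon)

  nouns_a <- .inflect_noun(c(
    "house", "home", "family", "mother", "father", "sister", "brother",
    "friend", "morning", "breakfast", "dinner", "kitchen", "garden", "street",
    "school", "store", "dog", "cat", "room", "window", "door", "table",
    "chair", "book", "story", "memory", "day", "week", "holiday", "birthday",
    "neighbor", "child", "game", "song", "picture", "letter", "phone",
    "coffee", "bread", "apple", "cousin", "aunt", "uncle", "grandmother",
    "grandfather", "bedroom", "blanket", "pillow", "candle", "flower",
    "lamp", "mirror"))
  nouns_b <- .inflect_noun(c(
    "factory", "machine", "engine", "office", "company", "market", "money",
    "river", "mountain", "forest", "ocean", "storm", "cloud", "winter",
    "summer", "road", "train", "station", "city", "bridge", "tower", "field",
    "farm", "harvest", "signal", "wire", "metal", "stone", "glass", "paper",
    "report", "meeting", "project", "system", "number", "record", "ticket",
    "journey", "harbor", "island", "warehouse", "crane", "cargo", "vessel",
    "anchor", "compass", "tunnel", "railway", "furnace", "turbine",
    "circuit", "lever"))
  verbs_a <- .inflect_verb(c(
    "walk", "talk", "play", "cook", "clean", "visit", "laugh", "smile",
    "remember", "enjoy", "help", "watch", "listen", "call", "stay", "live",
    "love", "like", "want", "need", "hug", "share", "greet", "chat",
    "relax", "rest", "dream"))
  verbs_b <- .inflect_verb(c(
    "work", "travel", "move", "carry", "build", "repair", "start", "stop",
    "turn", "push", "pull", "load", "measure", "count", "plan", "order",
    "deliver", "change", "open", "close", "weld", "drill", "haul", "steer",
    "dock", "forge", "grind"))
  adj_a <- c("happy", "warm", "small", "nice", "quiet", "young", "sweet",
             "funny", "gentle", "cozy", "friendly", "bright", "soft",
             "pleasant", "calm", "dear", "fresh", "lovely", "simple", "kind",
             "merry", "tender", "snug", "cheerful", "polite")
  adj_b <- c("cold", "large", "heavy", "fast", "slow", "loud", "busy",
             "distant", "grey", "rough", "sharp", "steep", "narrow", "wide",
             "deep", "empty", "solid", "rusty", "foggy", "windy",
             "bleak", "rigid", "coarse", "dense", "stark")
  adv_a <- c("really", "very", "always", "often", "usually", "together",
             "happily", "quietly", "gently", "slowly", "soon", "early",
             "yesterday", "today", "sometimes")
  adv_b <- c("quickly", "hardly", "barely", "far", "away", "late",
             "suddenly", "roughly", "loudly", "steadily", "rarely",
             "recently", "already", "almost", "nearly")
  determiners <- c("the", "a", "an", "this", "that", "these", "those",
                   "some", "any", "each", "every", "no", "another", "both",
                   "all", "either", "neither")
  prepositions <- c("of", "in", "on", "at", "by", "with", "from", "for",
                    "about", "into", "through", "between", "during", "after",
                    "before", "against", "around", "near", "under", "along")
  particles <- c("to", "up", "out", "off", "down", "back", "over")
  conjunctions <- c("and", "but", "or", "because", "so", "if", "when",
                    "while", "although", "since", "unless", "until")
  interjections <- c("um", "uh", "oh", "hey", "wow", "yeah", "hmm", "ugh",
                     "ouch", "well")
  wh_pronouns <- c("what", "who", "which", "whom", "something", "anything",
                   "everything", "nothing", "someone", "everyone")
  personal <- unlist(pronoun_lexicon(), use.names = FALSE)

  half <- function(x) rep(c("A", "B"), length.out = length(x))
  lex <- rbind(
    data.frame(word = nouns_a, pos = "noun", topic = "A"),
    data.frame(word = nouns_b, pos = "noun", topic = "B"),
    data.frame(word = verbs_a, pos = "verb", topic = "A"),
    data.frame(word = verbs_b, pos = "verb", topic = "B"),
    data.frame(word = adj_a, pos = "adjective", topic = "A"),
    data.frame(word = adj_b, pos = "adjective", topic = "B"),
    data.frame(word = adv_a, pos = "adverb", topic = "A"),
    data.frame(word = adv_b, pos = "adverb", topic = "B"),
    data.frame(word = determiners, pos = "determiner", topic = half(determiners)),
    data.frame(word = prepositions, pos = "preposition", topic = half(prepositions)),
    data.frame(word = particles, pos = "particle", topic = half(particles)),
    data.frame(word = conjunctions, pos = "conjunction", topic = half(conjunctions)),
    data.frame(word = interjections, pos = "interjection", topic = half(interjections)),
    data.frame(word = wh_pronouns, pos = "pronoun", topic = half(wh_pronouns)),
    data.frame(word = personal, pos = "pronoun", topic = half(personal))
  )
  lex <- lex[!duplicated(lex$word), , drop = FALSE]
  lex$pronoun_class <- .pronoun_class_of(lex$word)
  rownames(lex) <- NULL
  .lexicon_env$lexicon <- lex
  lex
}
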