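# Part-of-speech rate profiling: ten coarse categories per 100 words,
# through a pluggable tagger backend.

POS_CATEGORIES <- c("adverb", "determiner", "adjective", "pronoun",
                    "preposition", "particle", "conjunction", "noun",
                    "interjection", "verb")

#' Deterministic rule tagger over the built-in lexicon
#'
#' A closed-lexicon tagger: each lower-cased word token is looked up in
#' [builtin_lexicon()]; anything outside the lexicon is tagged `OTHER`.
#' Deterministic for fixed input by construction, so POS tests need no model
#' download. A production deployment would substitute a pretrained tagger
#' behind the same contract (a `tag` function returning one coarse label per
#' token, with the label set closed over the ten categories plus `OTHER`).
#'
#' @return A tagger backend: list with `name` and `tag(tokens)`.
#' @export
rule_tagger <- function() {
  lex <- builtin_lexicon()
  map <- stats::setNames(lex$pos, lex$word)
  tag <- function(tokens) {
    labels <- unname(map[tolower(tokens$text)])
    labels[is.na(labels)] <- "OTHER"
    # annotation tokens override the lexicon
    labels[tokens$kind %in% c("filler_um", "filler_uh")] <- "interjection"
    labels[tokens$kind %in% c("incomplete", "redaction", "laughter")] <- "OTHER"
    labels
  }
  list(name = "rule", tag = tag)
}

#' Tag all participant tokens of a transcript
#'
#' Only participant sentences are tagged. Filled pauses always map to
#' interjection; incomplete fragments, redactions and laughter marks map to
#' `OTHER` regardless of backend output.
#'
#' @param transcript A `speech_transcript`.
#' @param backend A tagger backend (see [rule_tagger()]).
#' @return Character vector of labels, one per participant token.
#' @export
tag_transcript <- function(transcript, backend = rule_tagger()) {
  sents <- Filter(function(s) s$speaker == "participant",
                  transcript_sentences(transcript))
  out <- vector("list", length(sents))
  for (i in seq_along(sents)) {
    toks <- sents[[i]]$tokens
    labels <- tryCatch(backend$tag(toks), error = function(e)
      stop(sprintf("tagger backend '%s' failed on sentence %d: %s",
                   backend$name, i, conditionMessage(e))))
    if (length(labels) != nrow(toks))
      stop(sprintf("tagger backend '%s' returned %d labels for %d tokens in sentence %d",
                   backend$name, length(labels), nrow(toks), i))
    bad <- setdiff(labels, c(POS_CATEGORIES, "OTHER"))
    if (length(bad))
      stop("tagger backend produced labels outside the closed set: ",
           paste(bad, collapse = ", "))
    labels[toks$kind %in% c("filler_um", "filler_uh")] <- "interjection"
    labels[toks$kind %in% c("incomplete", "redaction", "laughter")] <- "OTHER"
    out[[i]] <- labels
  }
  unlist(out) %||% character()
}

#' POS rates per 100 words from a label vector
#'
#' `rate_c = 100 * count_c / token_total` for each of the ten categories.
#' `OTHER` labels stay in the denominator but contribute to no numerator, so
#' the ten rates sum to at most 100.
#'
#' @param labels Character vector of coarse POS labels.
#' @param token_total Denominator (analyzable token count), > 0.
#' @return Named numeric vector of the ten rates.
#' @export
pos_rates <- function(labels, token_total) {
  if (!is.numeric(token_total) || token_total <= 0)
    stop("token_total must be positive")
  counts <- vapply(POS_CATEGORIES, function(cat) sum(labels == cat), 0)
  100 * counts / token_total
}

#' Per-participant POS profile
#'
#' Tags the participant's speech and converts label counts to per-100-word
#' rates over the analyzable token denominator (laughter and redactions
#' excluded; their `OTHER` labels are excluded from both numerator and
#' denominator).
#'
#' @param transcript A `speech_transcript`.
#' @param backend Tagger backend.
#' @return One-row data.frame: `participant_id` plus the ten `pos_*` rate
#'   columns.
#' @export
pos_profile <- function(transcript, backend = rule_tagger()) {
  labels <- tag_transcript(transcript, backend)
  toks <- participant_tokens(transcript)
  keep <- !toks$kind %in% c("laughter", "redaction")
  rates <- pos_rates(labels[keep], sum(keep))
  out <- data.frame(participant_id = transcript$participant_id,
                    t(rates), stringsAsFactors = FALSE)
  names(out) <- c("participant_id", paste0("pos_", POS_CATEGORIES))
  out
}
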