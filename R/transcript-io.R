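# Transcript data model: diarized, token-annotated interview speech.
#
# A Transcript is a list of Turns; a Turn holds ordered Sentences for one
# speaker; a Sentence holds a token table with disfluency annotations.
# Tokens are stored as a data.frame (one row per token) with columns:
#   text          surface form with terminal punctuation stripped
#   kind          one of word, filler_um, filler_uh, incomplete, laughter,
#                 redaction
#   pronoun_class one of first_sg, first_pl, second, third, none

TOKEN_KINDS <- c("word", "filler_um", "filler_uh", "incomplete", "laughter",
                 "redaction")
PRONOUN_CLASSES <- c("first_sg", "first_pl", "second", "third", "none")

#' Pronoun lexicons by class
#'
#' Fixed, case-insensitive lexicons mapping English pronoun surface forms to
#' the four pooled classes used throughout the package: first-person singular,
#' first-person plural, second person and third person. Subject, object,
#' possessive and reflexive forms are all included so that e.g. "I", "my" and
#' "me" pool into the same first-person-singular class.
#'
#' @return Named list of character vectors, one per pronoun class.
#' @export
pronoun_lexicon <- function() {
  list(
    first_sg = c("i", "me", "my", "mine", "myself"),
    first_pl = c("we", "us", "our", "ours", "ourselves"),
    second   = c("you", "your", "yours", "yourself", "yourselves"),
    third    = c("he", "him", "his", "himself",
                 "she", "her", "hers", "herself",
                 "they", "them", "their", "theirs", "themselves",
                 "it", "its", "itself")
  )
}

.pronoun_class_of <- function(lower) {
  lex <- pronoun_lexicon()
  out <- rep("none", length(lower))
  for (cls in names(lex)) out[lower %in% lex[[cls]]] <- cls
  out
}

#' Tokenize a verbatim utterance with disfluency annotations
#'
#' Splits on whitespace; each whitespace-delimited item yields exactly one
#' token. Terminal punctuation (`.?!,;:` and quotes) is stripped from word
#' edges; surface case is preserved while classification is case-insensitive.
#' Recognized annotation markers: `"um"`/`"uh"` filled pauses, a trailing
#' ASCII hyphen after at least one letter for an incomplete word (as in
#' `"sto-"`), `"[laughter]"`, and the privacy redactions `"[name]"` and
#' `"[date]"`.
#'
#' @param utterance Character scalar of plain transcribed text.
#' @return A token data.frame with columns `text`, `kind`, `pronoun_class`;
#'   zero rows for empty or whitespace-only input.
#' @examples
#' tokenize_utterance("I sto- stopped at the store.")
#' tokenize_utterance("um uh [laughter] [name]")
#' @export
tokenize_utterance <- function(utterance) {
  stopifnot(is.character(utterance), length(utterance) == 1L)
  empty <- data.frame(text = character(), kind = character(),
                      pronoun_class = character(), stringsAsFactors = FALSE)
  if (is.na(utterance) || !nzchar(trimws(utterance))) return(empty)
  raw <- strsplit(trimws(utterance), "\\s+")[[1]]
  # strip sentence punctuation from the edges, keep hyphens/brackets/apostrophes
  surf <- gsub("^[\".,!?;:()]+|[\".,!?;:()]+$", "", raw)
  keep <- nzchar(surf)
  surf <- surf[keep]
  if (!length(surf)) return(empty)
  lower <- tolower(surf)
  kind <- rep("word", length(surf))
  kind[lower == "um"] <- "filler_um"
  kind[lower == "uh"] <- "filler_uh"
  kind[grepl("^[[:alpha:]']*[[:alpha:]]-$", surf)] <- "incomplete"
  kind[lower == "[laughter]"] <- "laughter"
  kind[lower %in% c("[name]", "[date]")] <- "redaction"
  pron <- .pronoun_class_of(lower)
  pron[kind != "word"] <- "none"
  data.frame(text = surf, kind = kind, pronoun_class = pron,
             stringsAsFactors = FALSE)
}

#' Split a turn's text at transcriber punctuation
#'
#' Splits only at terminal punctuation marks (`.`, `?`, `!`) placed by the
#' transcriber. Filled pauses, repeated words and hyphen-marked incomplete
#' fragments never cause a split, avoiding the spurious segment boundaries
#' that automatic sentence splitters introduce in disfluent speech. A trailing
#' fragment without terminal punctuation becomes a final sentence.
#'
#' @param turn_text Character scalar.
#' @return Character vector of sentence strings (terminal punctuation kept).
#' @examples
#' split_sentences("I went home. It was late.")
#' split_sentences("I sto- stopped at the store.")
#' @export
split_sentences <- function(turn_text) {
  stopifnot(is.character(turn_text), length(turn_text) == 1L)
  if (is.na(turn_text) || !nzchar(trimws(turn_text))) return(character())
  m <- regmatches(turn_text,
                  gregexpr("[^.?!]+[.?!]+|[^.?!]+$", turn_text))[[1]]
  m <- trimws(m)
  m[nzchar(m)]
}

.terminal_punct <- function(sentence_text) {
  m <- regmatches(sentence_text, regexpr("[.?!]+$", sentence_text))
  if (length(m)) m else ""
}

.new_sentence <- function(text, speaker) {
  term <- .terminal_punct(text)
  body <- sub("[.?!]+$", "", text)
  list(tokens = tokenize_utterance(body), speaker = speaker, terminal = term)
}

.new_turn <- function(speaker, text) {
  sents <- lapply(split_sentences(text), .new_sentence, speaker = speaker)
  list(speaker = speaker, sentences = sents)
}

#' @export
print.speech_transcript <- function(x, ...) {
  cat(sprintf("<speech_transcript> participant %s (%s): %d turns, %d participant words\n",
              x$participant_id, x$group, length(x$turns),
              participant_token_total(x)))
  invisible(x)
}

.speaker_code <- c(I = "interviewer", P = "participant")

#' Parse a diarized transcript from the package JSON schema
#'
#' The schema is a JSON object
#' `{participant_id, group, cohort, metadata{age,sex,race,education_years},
#'   turns:[{speaker:"I"|"P", text}]}`.
#' Adjacent turns with the same speaker are merged into one turn (so that
#' interviewer back-channels logged as separate segments do not fragment the
#' dialogue), then each turn is sentence-split at transcriber punctuation and
#' tokenized. The raw turn list is preserved under `$provenance`.
#'
#' @param source Path to a JSON file, a JSON string, or an already-decoded
#'   list with the same fields.
#' @return A `speech_transcript` object.
#' @export
parse_transcript <- function(source) {
  doc <- if (is.list(source)) {
    source
  } else {
    jsonlite::fromJSON(source, simplifyDataFrame = FALSE)
  }
  if (is.null(doc$turns) || length(doc$turns) == 0L)
    stop("transcript document has no turns")
  if (is.null(doc$participant_id)) stop("transcript document has no participant_id")
  group <- doc$group %||% "unknown"
  if (!group %in% c("SSD", "HC", "unknown"))
    stop(sprintf("unknown group label '%s'", group))
  for (i in seq_along(doc$turns)) {
    sp <- doc$turns[[i]]$speaker
    if (is.null(sp) || !sp %in% c("I", "P"))
      stop(sprintf("turn %d has invalid speaker '%s' (must be \"I\" or \"P\")",
                   i, if (is.null(sp)) "<missing>" else sp))
    if (is.null(doc$turns[[i]]$text))
      stop(sprintf("turn %d has no text field", i))
  }
  speakers <- vapply(doc$turns, function(t) t$speaker, "")
  texts <- vapply(doc$turns, function(t) as.character(t$text), "")
  # merge adjacent same-speaker turns
  runs <- rle(speakers)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  turns <- vector("list", length(runs$values))
  for (k in seq_along(runs$values)) {
    merged <- paste(texts[idx_start[k]:idx_end[k]], collapse = " ")
    turns[[k]] <- .new_turn(.speaker_code[[runs$values[k]]], merged)
  }
  turns <- Filter(function(t) length(t$sentences) > 0L, turns)
  structure(list(
    participant_id = as.character(doc$participant_id),
    group = group,
    cohort = if (is.null(doc$cohort)) NA_character_ else as.character(doc$cohort),
    metadata = doc$metadata %||% list(),
    turns = turns,
    provenance = lapply(seq_along(doc$turns), function(i)
      list(speaker = speakers[i], text = texts[i]))
  ), class = "speech_transcript")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.sentence_text <- function(sentence) {
  paste0(paste(sentence$tokens$text, collapse = " "),
         if (nzchar(sentence$terminal)) sentence$terminal else ".")
}

.turn_text <- function(turn) {
  paste(vapply(turn$sentences, .sentence_text, ""), collapse = " ")
}

#' Serialize a transcript back to the package JSON schema
#'
#' @param transcript A `speech_transcript`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
serialize_transcript <- function(transcript, path = NULL) {
  stopifnot(inherits(transcript, "speech_transcript"))
  speaker_abbr <- c(interviewer = "I", participant = "P")
  doc <- list(
    participant_id = transcript$participant_id,
    group = transcript$group,
    cohort = transcript$cohort,
    metadata = transcript$metadata,
    turns = lapply(transcript$turns, function(t)
      list(speaker = speaker_abbr[[t$speaker]], text = .turn_text(t)))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read a Transcriber-style XML transcript
#'
#' Minimal reader for the speaker-segmented XML dialect produced by the
#' Transcriber annotation tool: `<Turn speaker=...>` elements inside
#' `<Episode>/<Section>`, with speaker ids resolved through the `<Speakers>`
#' table when present. Speakers whose name or id contains "int" are treated
#' as the interviewer; everything else as the participant. Unrecognized
#' markup inside turns is skipped with a warning.
#'
#' @param path Path to the XML file.
#' @param participant_id Participant identifier to attach.
#' @param group Group label (`"SSD"`, `"HC"` or `"unknown"`).
#' @return A `speech_transcript`.
#' @export
read_transcriber_xml <- function(path, participant_id = "unknown",
                                 group = "unknown") {
  doc <- xml2::read_xml(path)
  spk_nodes <- xml2::xml_find_all(doc, ".//Speakers/Speaker")
  spk_map <- stats::setNames(
    tolower(xml2::xml_attr(spk_nodes, "name")),
    xml2::xml_attr(spk_nodes, "id"))
  turn_nodes <- xml2::xml_find_all(doc, ".//Turn")
  if (!length(turn_nodes)) stop("no <Turn> elements found in ", path)
  turns <- list()
  for (node in turn_nodes) {
    spk_id <- xml2::xml_attr(node, "speaker")
    label <- if (!is.na(spk_id) && spk_id %in% names(spk_map))
      spk_map[[spk_id]] else tolower(spk_id %||% "")
    role <- if (grepl("int", label)) "I" else "P"
    kids <- xml2::xml_contents(node)
    texts <- character()
    for (kid in kids) {
      nm <- xml2::xml_name(kid)
      if (nm == "text") {
        texts <- c(texts, xml2::xml_text(kid))
      } else if (nm %in% c("Sync", "Comment", "Who", "Background", "Event")) {
        # timing/markup nodes carry no speech
      } else {
        warning(sprintf("skipping unrecognized markup <%s> in %s", nm, path))
      }
    }
    txt <- trimws(paste(texts, collapse = " "))
    if (nzchar(txt)) turns <- c(turns, list(list(speaker = role, text = txt)))
  }
  parse_transcript(list(participant_id = participant_id, group = group,
                        turns = turns))
}

#' All sentences of a transcript in spoken order
#'
#' @param transcript A `speech_transcript`.
#' @return List of sentence objects (each with `$tokens`, `$speaker`).
#' @export
transcript_sentences <- function(transcript) {
  do.call(c, lapply(transcript$turns, function(t) t$sentences))
}

#' Participant token table of a transcript
#'
#' Concatenated token rows over all participant sentences.
#' @param transcript A `speech_transcript`.
#' @return Token data.frame.
#' @export
participant_tokens <- function(transcript) {
  sents <- Filter(function(s) s$speaker == "participant",
                  transcript_sentences(transcript))
  if (!length(sents))
    return(data.frame(text = character(), kind = character(),
                      pronoun_class = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(sents, `[[`, "tokens"))
}

#' Count of analyzable participant tokens
#'
#' The per-100-word rate denominator used throughout the package: all
#' participant tokens except laughter marks and privacy redaction
#' placeholders. Filled pauses and incomplete-word fragments count as words.
#'
#' @param transcript A `speech_transcript`.
#' @return Integer count.
#' @export
participant_token_total <- function(transcript) {
  toks <- participant_tokens(transcript)
  sum(!toks$kind %in% c("laughter", "redaction"))
}

#' Extract prompt-anchored dialogue exchanges
#'
#' An exchange is an interviewer prompt turn followed by all participant
#' sentences uttered before the interviewer speaks again. Participant
#' sentences carry `index_in_turn` 1..k, their distance from the prompt.
#' Participant speech preceding the first interviewer prompt belongs to no
#' exchange and is reported via a message; a trailing prompt with no response
#' yields no exchange.
#'
#' @param transcript A `speech_transcript`.
#' @return List of exchanges, each `list(prompt = <turn>, responses =
#'   <sentence list>)` with responses annotated with `$index_in_turn`.
#' @export
extract_exchanges <- function(transcript) {
  turns <- transcript$turns
  speakers <- vapply(turns, `[[`, "", "speaker")
  if (!any(speakers == "interviewer")) {
    warning("transcript has no interviewer turns; no exchanges extracted")
    return(list())
  }
  first_i <- which(speakers == "interviewer")[1]
  if (first_i > 1L)
    message(sprintf(
      "participant %s: %d participant turn(s) precede the first prompt; excluded from exchanges",
      transcript$participant_id, first_i - 1L))
  exchanges <- list()
  i <- first_i
  while (i <= length(turns)) {
    if (speakers[i] != "interviewer") { i <- i + 1L; next }
    j <- i + 1L
    responses <- list()
    while (j <= length(turns) && speakers[j] == "participant") {
      responses <- c(responses, turns[[j]]$sentences)
      j <- j + 1L
    }
    if (length(responses)) {
      for (k in seq_along(responses)) responses[[k]]$index_in_turn <- k
      exchanges <- c(exchanges, list(list(prompt = turns[[i]],
                                          responses = responses)))
    }
    i <- j
  }
  exchanges
}

#' Read per-participant clinical ratings from CSV
#'
#' Expected columns: `participant_id`, `tlc_item_1` .. `tlc_item_18`,
#' `tlc_global`. A `tlc_total` column is recomputed from the items with
#' [tlc_total()] (2 x sum of items 1-11 plus sum of items 12-18).
#'
#' @param path CSV file path.
#' @return data.frame with item columns, `tlc_global` and `tlc_total`.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  item_cols <- paste0("tlc_item_", 1:18)
  missing <- setdiff(c("participant_id", item_cols, "tlc_global"), names(df))
  if (length(missing))
    stop("ratings CSV missing columns: ", paste(missing, collapse = ", "))
  df$tlc_total <- apply(df[item_cols], 1L, tlc_total)
  df
}
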