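test_that("tokenizer classifies markers and assigns pronoun classes", {
  toks <- tokenize_utterance("I sto- stopped at the store")
  expect_equal(nrow(toks), 6L)
  expect_equal(sum(toks$kind == "incomplete"), 1L)
  expect_equal(toks$text[toks$kind == "incomplete"], "sto-")

  toks <- tokenize_utterance("I my me we")
  expect_equal(toks$pronoun_class,
               c("first_sg", "first_sg", "first_sg", "first_pl"))

  toks <- tokenize_utterance("um uh [laughter] [name]")
  expect_equal(toks$kind,
               c("filler_um", "filler_uh", "laughter", "redaction"))
  # pronoun class only for plain words
  expect_true(all(toks$pronoun_class == "none"))

  expect_equal(nrow(tokenize_utterance("   ")), 0L)
  # kind == incomplete iff the surface ends with the hyphen marker
  mixed <- tokenize_utterance("sto- - stop-ped you.")
  expect_equal(mixed$kind[mixed$text == "sto-"], "incomplete")
  expect_false(any(mixed$kind == "incomplete" & !grepl("-$", mixed$text)))
})

test_that("tokenization is deterministic and case-insensitive for matching", {
  u <- "UM Uh I MY [Laughter]"
  t1 <- tokenize_utterance(u); t2 <- tokenize_utterance(u)
  expect_identical(t1, t2)
  expect_equal(t1$kind[1:2], c("filler_um", "filler_uh"))
  expect_equal(t1$text[1], "UM")  # surface case preserved
})

test_that("sentence splitting respects transcriber punctuation only", {
  expect_length(split_sentences("I went home. It was late."), 2L)
  expect_length(split_sentences("I sto- stopped at the store."), 1L)
  expect_equal(split_sentences("Why? Because."), c("Why?", "Because."))
  expect_length(split_sentences("no punctuation here"), 1L)
  expect_length(split_sentences(""), 0L)
})

test_that("parse_transcript builds, merges and validates turns", {
  tr <- make_transcript(list(list(speaker = "I", text = "How are you?"),
                             list(speaker = "P", text = "I am fine.")))
  expect_length(tr$turns, 2L)
  expect_equal(participant_token_total(tr), 3L)

  merged <- make_transcript(list(list(speaker = "I", text = "Hello."),
                                 list(speaker = "I", text = "How are you?"),
                                 list(speaker = "P", text = "Fine.")))
  expect_length(merged$turns, 2L)
  expect_length(merged$turns[[1]]$sentences, 2L)

  expect_error(make_transcript(list(list(speaker = "X", text = "hi."))),
               "turn 1")
  expect_error(parse_transcript(list(participant_id = "p", turns = list())),
               "no turns")
  expect_error(make_transcript(list(list(speaker = "I", text = "hi.")),
                               group = "CTRL"), "group")
})

test_that("serialize/parse round-trips speakers, order and token surfaces", {
  corp <- generate_corpus(ssd_hc_preset(n_per_group = c(2, 2),
                                        n_exchanges = 3,
                                        sentences_per_exchange = 2, seed = 5))
  for (tr in corp$transcripts[c(1, 3)]) {
    rt <- parse_transcript(serialize_transcript(tr))
    expect_equal(length(rt$turns), length(tr$turns))
    expect_equal(vapply(rt$turns, `[[`, "", "speaker"),
                 vapply(tr$turns, `[[`, "", "speaker"))
    tok <- function(x) do.call(rbind, lapply(transcript_sentences(x),
                                             `[[`, "tokens"))
    expect_equal(tok(rt), tok(tr))
    # no token lost or duplicated by sentence splitting
    expect_equal(sum(vapply(transcript_sentences(rt),
                            function(s) nrow(s$tokens), 0L)),
                 nrow(tok(tr)))
  }
})

test_that("extract_exchanges anchors responses to prompts", {
  tr <- make_transcript(list(
    list(speaker = "I", text = "Question one?"),
    list(speaker = "P", text = "Answer. More answer."),
    list(speaker = "I", text = "Question two?"),
    list(speaker = "P", text = "Short.")))
  ex <- extract_exchanges(tr)
  expect_length(ex, 2L)
  expect_length(ex[[1]]$responses, 2L)
  expect_length(ex[[2]]$responses, 1L)
  expect_equal(vapply(ex[[1]]$responses, `[[`, 0L, "index_in_turn"), 1:2)

  # trailing prompt with no response is not an exchange
  tr2 <- make_transcript(list(
    list(speaker = "I", text = "Q?"), list(speaker = "P", text = "A."),
    list(speaker = "I", text = "Anything else?")))
  expect_length(extract_exchanges(tr2), 1L)

  # participant-first speech excluded from exchanges but logged
  tr3 <- make_transcript(list(
    list(speaker = "P", text = "Unprompted words here."),
    list(speaker = "I", text = "Q?"), list(speaker = "P", text = "A.")))
  expect_message(ex3 <- extract_exchanges(tr3), "precede")
  expect_length(ex3, 1L)
  expect_length(ex3[[1]]$responses, 1L)
  # ...but retained for lexical statistics
  expect_equal(participant_token_total(tr3), 4L)

  tr4 <- make_transcript(list(list(speaker = "P", text = "Only me talking.")))
  expect_warning(ex4 <- extract_exchanges(tr4), "no interviewer")
  expect_length(ex4, 0L)
})

test_that("Transcriber-style XML reader maps speakers and skips junk", {
  xml <- c('<?xml version="1.0"?>',
           '<Trans><Speakers>',
           '<Speaker id="spk1" name="Interviewer"/>',
           '<Speaker id="spk2" name="Subject"/>',
           '</Speakers><Episode><Section>',
           '<Turn speaker="spk1"><Sync time="0.0"/>How are you today?</Turn>',
           '<Turn speaker="spk2"><Sync time="2.1"/>I am fine. Really.',
           '<Blob>???</Blob></Turn>',
           '</Section></Episode></Trans>')
  path <- withr::local_tempfile(fileext = ".trs")
  writeLines(xml, path)
  expect_warning(tr <- read_transcriber_xml(path, participant_id = "x1",
                                            group = "HC"), "Blob")
  expect_length(tr$turns, 2L)
  expect_equal(tr$turns[[1]]$speaker, "interviewer")
  expect_equal(participant_token_total(tr), 4L)
})

test_that("ratings CSV reader recomputes the total", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(participant_id = "p1",
                   t(stats::setNames(rep(1L, 18), paste0("tlc_item_", 1:18))),
                   tlc_global = 1L)
  write.csv(df, path, row.names = FALSE)
  rt <- read_ratings_csv(path)
  expect_equal(rt$tlc_total, 29L)
  write.csv(df[, -2], path, row.names = FALSE)
  expect_error(read_ratings_csv(path), "missing columns")
})
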