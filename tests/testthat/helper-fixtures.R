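# Shared fixtures: tiny hand-built transcripts and stub backends.

make_transcript <- function(turns, id = "p1", group = "unknown",
                            metadata = list()) {
  parse_transcript(list(participant_id = id, group = group,
                        metadata = metadata, turns = turns))
}

# two-group mini corpus with hand-controlled utterances
mini_corpus <- function() {
  a <- make_transcript(list(
    list(speaker = "I", text = "What about your family?"),
    list(speaker = "P", text = "I sto- stopped at the store. I was um tired.")
  ), id = "A1", group = "SSD")
  b <- make_transcript(list(
    list(speaker = "I", text = "What about your family?"),
    list(speaker = "P", text = "We went home together. We um cooked dinner.")
  ), id = "B1", group = "HC")
  list(a, b)
}

# sentence object with n filler-free words, for length-sensitive tests
stub_sentence <- function(n_words, speaker = "participant", index = NULL) {
  toks <- tokenize_utterance(paste(rep("home", n_words), collapse = " "))
  s <- list(tokens = toks, speaker = speaker, terminal = ".")
  if (!is.null(index)) s$index_in_turn <- index
  s
}

# backend whose nsp is keyed by the second sentence's word count
stub_nsp_backend <- function(prob_by_len) {
  list(name = "stub",
       embed_words = function(words) stop("not used"),
       nsp = function(w1, w2) prob_by_len[[as.character(length(w2))]])
}

# direct double-precision re-implementation of the weighted log-odds
# formula, kept independent of the package code path
wlo_direct <- function(y_a, y_b, n_a, n_b, alpha0, pooled_total) {
  a_w <- alpha0 * (y_a + y_b) / pooled_total
  delta <- log((y_a + a_w) / (n_a + alpha0 - y_a - a_w)) -
    log((y_b + a_w) / (n_b + alpha0 - y_b - a_w))
  v <- 1 / (y_a + a_w) + 1 / (y_b + a_w)
  list(delta = delta, variance = v, z = delta / sqrt(v))
}

# full-size preset corpus and its study report, computed once and shared
# across test files (15/group at ~1750 words each is the stated world the
# recovery invariants refer to)
.shared_fixtures <- new.env()
preset_corpus <- function() {
  if (is.null(.shared_fixtures$corpus))
    .shared_fixtures$corpus <- generate_corpus(
      ssd_hc_preset(n_per_group = c(15, 15), seed = 1))
  .shared_fixtures$corpus
}
preset_report <- function() {
  if (is.null(.shared_fixtures$report))
    .shared_fixtures$report <- suppressMessages(
      run_study(preset_corpus(), seed = 1))
  .shared_fixtures$report
}

# brute-force AUC by pair enumeration
auc_bruteforce <- function(scores, labels) {
  y <- factor(labels)
  pos <- scores[y == levels(y)[2]]
  neg <- scores[y == levels(y)[1]]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}
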