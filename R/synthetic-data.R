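# Synthetic diarized-transcript corpora with controllable group effects.
#
# The generator emulates two-group clinical interview corpora: interviewer
# prompts drawn from topic A, participant bag-of-words sentences whose topic
# mixture drifts from A toward B with distance from the prompt (drift slope 0
# = stationary), per-group POS category mixes, pronoun-class mixes, uh:um
# filled-pause mixes, incomplete-word and laughter rates, and zero-inflated
# clinician rating items. Output is deterministic given (config, seed) and is
# written in the package transcript JSON schema, so every downstream stage
# can be exercised hermetically.

.validate_probs <- function(p, name) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop(sprintf("%s must be nonnegative and sum to 1", name))
}

#' Generator configuration
#'
#' Builds a validated configuration for [generate_corpus()]. `groups` is a
#' two-element named list; each element sets, for that group:
#' `pos_mix` (probabilities over the ten POS categories), `pronoun_class`
#' (probabilities over first_sg/first_pl/second/third/other),
#' `uh_um_mix` (probability that a filled pause is "uh"), `filler_share`
#' (fraction of interjection slots realized as filled pauses),
#' `incomplete_prob` (per-word probability of an abandoned fragment, as in
#' "sto- stopped"), `laughter_prob` (per sentence), `drift_slope` (topic
#' mixing added per sentence position; 0 = stationary), `drift_start`
#' (initial off-topic mixing at position 1, default 0), `words_per_sentence`
#' (Poisson mean), `education_mean`/`education_sd` (years), and `tlc`
#' (zero-inflated item distribution: `p_zero`, `lambda`, `n_elevated`,
#' `elevated_p_zero`, `elevated_lambda`).
#'
#' @param n_per_group Integer vector of length 2 (participants per group).
#' @param n_exchanges Interviewer prompts per participant.
#' @param sentences_per_exchange Poisson mean of response sentences per
#'   prompt (at least 1 is always produced).
#' @param groups Named two-element list of per-group settings (see above).
#' @param seed Integer seed; fully determines the corpus.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_group = c(15L, 15L), n_exchanges = 15L,
                             sentences_per_exchange = 5, groups, seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1L),
            length(groups) == 2L, !is.null(names(groups)))
  for (g in names(groups)) {
    cfg <- groups[[g]]
    .validate_probs(cfg$pos_mix, paste0(g, "$pos_mix"))
    .validate_probs(cfg$pronoun_class, paste0(g, "$pronoun_class"))
    for (p in c("uh_um_mix", "filler_share", "incomplete_prob", "laughter_prob"))
      if (cfg[[p]] < 0 || cfg[[p]] > 1)
        stop(sprintf("%s$%s must be in [0, 1]", g, p))
    if (cfg$drift_slope < 0) stop(g, "$drift_slope must be >= 0")
    if ((cfg$drift_start %||% 0) < 0) stop(g, "$drift_start must be >= 0")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_exchanges = as.integer(n_exchanges),
                 sentences_per_exchange = sentences_per_exchange,
                 groups = groups, seed = as.integer(seed)),
            class = "generator_config")
}

.group_settings <- function(pos_mix, pronoun_class, uh_um_mix,
                            incomplete_prob, laughter_prob, drift_slope,
                            words_per_sentence, education_mean, education_sd,
                            tlc, filler_share = 0.55, pos_jitter_sd = 0.08,
                            drift_start = 0) {
  list(pos_mix = pos_mix / sum(pos_mix),
       pronoun_class = pronoun_class / sum(pronoun_class),
       uh_um_mix = uh_um_mix, filler_share = filler_share,
       incomplete_prob = incomplete_prob, laughter_prob = laughter_prob,
       drift_slope = drift_slope, drift_start = drift_start,
       words_per_sentence = words_per_sentence,
       education_mean = education_mean, education_sd = education_sd,
       tlc = tlc, pos_jitter_sd = pos_jitter_sd)
}

# POS mixes: group means of the per-100-word rate profile being emulated,
# renormalized over the ten categories.
.POS_MIX_SSD <- c(adverb = 8.11, determiner = 6.53, adjective = 6.19,
                  pronoun = 13.41, preposition = 7.97, particle = 2.35,
                  conjunction = 4.61, noun = 13.67, interjection = 6.35,
                  verb = 19.55)
.POS_MIX_HC <- c(adverb = 10.65, determiner = 7.50, adjective = 7.10,
                 pronoun = 11.77, preposition = 8.84, particle = 2.65,
                 conjunction = 5.33, noun = 13.16, interjection = 6.07,
                 verb = 19.34)

#' Two-group preset with the qualitative effect pattern under study
#'
#' Group `SSD` (A side): more pronouns with a first-person-singular tilt,
#' fewer adverbs/adjectives/determiners, filled pauses dominated by "uh"
#' (0.8 vs 0.3), a strongly elevated incomplete-word probability (0.03 vs
#' 0.002), less laughter, an initial off-topic offset plus a positive
#' topic-drift slope (responses begin off the prompt topic and wander off
#' the prompt topic) and a mostly-zero clinician rating distribution with a
#' few elevated participants. Group `HC` (B side): first-person-plural tilt,
#' "um"-dominant, near-zero incomplete rate, stationary topics, all-but-zero
#' ratings. Sentence-length means differ (14.4 vs 17.5 words) as in the
#' emulated recordings.
#'
#' Sizes default to 15 participants per group, 18 prompts per participant
#' and a Poisson(6) response-sentence count, giving roughly 1500-1900 words
#' per participant as in the recordings being emulated.
#'
#' @param n_per_group Participants per group, default 15 each.
#' @param seed Integer seed.
#' @param n_exchanges Prompts per participant.
#' @param sentences_per_exchange Poisson mean response sentences.
#' @return A `generator_config`.
#' @export
ssd_hc_preset <- function(n_per_group = c(15L, 15L), seed = 1L,
                          n_exchanges = 18L, sentences_per_exchange = 6) {
  groups <- list(
    SSD = .group_settings(
      pos_mix = .POS_MIX_SSD,
      pronoun_class = c(first_sg = 0.55, first_pl = 0.04, second = 0.18,
                        third = 0.18, other = 0.05),
      uh_um_mix = 0.8, incomplete_prob = 0.03, laughter_prob = 0.05,
      # responses BEGIN well off the prompt topic (drift_start) and wander
      # gently further off with each sentence (drift_slope); the level
      # effect dominates the slope, keeping the trajectory near-linear
      drift_slope = 0.015, drift_start = 0.12, words_per_sentence = 14.4,
      education_mean = 13.4, education_sd = 2.5,
      # ratings are mostly zero in BOTH groups (subclinical disturbance);
      # only the few elevated participants depart from zero
      tlc = list(p_zero = 0.97, lambda = 0.5, n_elevated = 4L,
                 elevated_p_zero = 0.3, elevated_lambda = 1.5),
      pos_jitter_sd = 0.06),
    HC = .group_settings(
      pos_mix = .POS_MIX_HC,
      pronoun_class = c(first_sg = 0.33, first_pl = 0.22, second = 0.12,
                        third = 0.25, other = 0.08),
      uh_um_mix = 0.3, incomplete_prob = 0.002, laughter_prob = 0.15,
      drift_slope = 0, words_per_sentence = 17.5,
      education_mean = 15.8, education_sd = 2.2,
      tlc = list(p_zero = 0.98, lambda = 0.5, n_elevated = 0L,
                 elevated_p_zero = 0.3, elevated_lambda = 1.5),
      pos_jitter_sd = 0.06)
  )
  generator_config(n_per_group = n_per_group, n_exchanges = n_exchanges,
                   sentences_per_exchange = sentences_per_exchange,
                   groups = groups, seed = seed)
}

#' Null preset: two groups drawn from one population
#'
#' Both groups use identical (HC-like) settings — no POS, pronoun, filler,
#' disfluency, drift or rating differences, identical demographic
#' distributions. Used for type-I-error calibration of the statistics
#' battery and null classifier runs.
#'
#' @inheritParams ssd_hc_preset
#' @return A `generator_config`.
#' @export
null_preset <- function(n_per_group = c(15L, 15L), seed = 1L,
                        n_exchanges = 15L, sentences_per_exchange = 5) {
  base <- .group_settings(
    pos_mix = .POS_MIX_HC,
    pronoun_class = c(first_sg = 0.33, first_pl = 0.22, second = 0.12,
                      third = 0.25, other = 0.08),
    uh_um_mix = 0.5, incomplete_prob = 0.01, laughter_prob = 0.1,
    drift_slope = 0, words_per_sentence = 16,
    education_mean = 15, education_sd = 2.3,
    tlc = list(p_zero = 0.95, lambda = 0.5, n_elevated = 0L,
               elevated_p_zero = 0.3, elevated_lambda = 1.5))
  generator_config(n_per_group = n_per_group, n_exchanges = n_exchanges,
                   sentences_per_exchange = sentences_per_exchange,
                   groups = list(A = base, B = base), seed = seed)
}

# Pre-split lexicon pools for fast sampling.
.lexicon_pools <- function() {
  if (!is.null(.lexicon_env$pools)) return(.lexicon_env$pools)
  lex <- builtin_lexicon()
  content <- c("noun", "verb", "adjective", "adverb")
  pools <- list(content = list(), fun = list(), pron = list())
  for (cat in content)
    for (t in c("A", "B"))
      pools$content[[paste0(cat, ".", t)]] <-
        lex$word[lex$pos == cat & lex$topic == t]
  for (cat in c("determiner", "preposition", "particle", "conjunction"))
    pools$fun[[cat]] <- lex$word[lex$pos == cat]
  pools$fun$interjection <-
    lex$word[lex$pos == "interjection" & !lex$word %in% c("um", "uh")]
  for (cls in c("first_sg", "first_pl", "second", "third"))
    pools$pron[[cls]] <- lex$word[lex$pos == "pronoun" & lex$pronoun_class == cls]
  pools$pron$other <- lex$word[lex$pos == "pronoun" & lex$pronoun_class == "none"]
  .lexicon_env$pools <- pools
  pools
}

# One participant sentence as a text string: bag-of-words sampling from the
# per-group mixes, with topic mixing (1-m)A + mB for content words, pronoun
# class selection, filled pauses, abandoned fragments, and a laughter mark.
.sample_sentence <- function(n_words, pos_mix, g, m, pools) {
  cats <- sample(names(pos_mix), n_words, replace = TRUE, prob = pos_mix)
  words <- character(n_words)
  for (i in seq_len(n_words)) {
    cat_i <- cats[i]
    words[i] <- if (cat_i %in% c("noun", "verb", "adjective", "adverb")) {
      t <- if (stats::runif(1) < m) "B" else "A"
      sample(pools$content[[paste0(cat_i, ".", t)]], 1L)
    } else if (cat_i == "pronoun") {
      cls <- sample(names(g$pronoun_class), 1L, prob = g$pronoun_class)
      sample(pools$pron[[cls]], 1L)
    } else if (cat_i == "interjection") {
      if (stats::runif(1) < g$filler_share) {
        if (stats::runif(1) < g$uh_um_mix) "uh" else "um"
      } else sample(pools$fun$interjection, 1L)
    } else {
      sample(pools$fun[[cat_i]], 1L)
    }
  }
  words[words == "i"] <- "I"
  # abandoned fragments: "sto-" inserted before the completed word
  frag <- stats::runif(n_words) < g$incomplete_prob
  if (any(frag)) {
    out <- character(0)
    for (i in seq_len(n_words)) {
      if (frag[i])
        out <- c(out, paste0(substr(words[i], 1L, min(3L, nchar(words[i]))), "-"))
      out <- c(out, words[i])
    }
    words <- out
  }
  if (stats::runif(1) < g$laughter_prob) words <- c(words, "[laughter]")
  paste0(paste(words, collapse = " "), ".")
}

.sample_prompt <- function(pools) {
  n <- 6L + stats::rpois(1L, 4)
  mix <- c(pronoun = 0.15, verb = 0.2, noun = 0.22, determiner = 0.12,
           preposition = 0.11, adjective = 0.08, adverb = 0.05,
           conjunction = 0.05, second = 0.02)
  cats <- sample(names(mix), n, replace = TRUE, prob = mix)
  words <- vapply(cats, function(cat_i) {
    if (cat_i %in% c("noun", "verb", "adjective", "adverb"))
      sample(pools$content[[paste0(cat_i, ".A")]], 1L)
    else if (cat_i == "pronoun") sample(pools$pron$other, 1L)
    else if (cat_i == "second") sample(pools$pron$second, 1L)
    else sample(pools$fun[[cat_i]], 1L)
  }, "")
  paste0(paste(words, collapse = " "), "?")
}

.sample_tlc <- function(tlc, elevated) {
  p0 <- if (elevated) tlc$elevated_p_zero else tlc$p_zero
  lam <- if (elevated) tlc$elevated_lambda else tlc$lambda
  items <- ifelse(stats::runif(18) < p0, 0L,
                  pmin(4L, 1L + stats::rpois(18, lam)))
  global <- if (elevated) sample(2:3, 1L)
            else if (any(items > 0) && stats::runif(1) < 0.5) 1L else 0L
  list(items = as.integer(items), global = as.integer(global))
}

#' Generate a two-group synthetic corpus with clinician-style ratings
#'
#' Deterministic given the config's seed. Each participant gets
#' `n_exchanges` interviewer prompts (topic-A questions); each prompt is
#' followed by a Poisson number of participant sentences whose content-word
#' topic mixture is `(1-m_j) A + m_j B` with
#' `m_j = min(drift_start + drift_slope * j, 1)` at sentence position j.
#'
#' @param config A `generator_config` (see [ssd_hc_preset()],
#'   [null_preset()]).
#' @return List with `transcripts` (list of `speech_transcript`) and
#'   `ratings` (data.frame: `participant_id`, `tlc_item_1..18`,
#'   `tlc_global`, `tlc_total`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  pools <- .lexicon_pools()
  with_seed(config$seed, {
    transcripts <- list()
    ratings <- list()
    for (gi in 1:2) {
      gname <- names(config$groups)[gi]
      g <- config$groups[[gi]]
      n <- config$n_per_group[gi]
      elevated_ids <- if (g$tlc$n_elevated > 0L)
        sample.int(n, min(g$tlc$n_elevated, n)) else integer()
      for (p in seq_len(n)) {
        pid <- sprintf("%s%02d", gname, p)
        pos_mix <- g$pos_mix * exp(stats::rnorm(10, 0, g$pos_jitter_sd))
        pos_mix <- pos_mix / sum(pos_mix)
        turn_specs <- list()
        for (ex in seq_len(config$n_exchanges)) {
          prompt <- .sample_prompt(pools)
          k <- 1L + stats::rpois(1L, max(config$sentences_per_exchange - 1, 0))
          sents <- vapply(seq_len(k), function(j) {
            m <- min((g$drift_start %||% 0) + g$drift_slope * j, 1)
            L <- max(3L, stats::rpois(1L, g$words_per_sentence))
            .sample_sentence(L, pos_mix, g, m, pools)
          }, "")
          turn_specs <- c(turn_specs,
                          list(list(speaker = "I", text = prompt)),
                          list(list(speaker = "P",
                                    text = paste(sents, collapse = " "))))
        }
        meta <- list(
          age = round(stats::rnorm(1, 36, 6.5)),
          sex = sample(c("female", "male"), 1L),
          race = sample(c("african_american", "asian", "caucasian"), 1L,
                        prob = c(0.45, 0.05, 0.5)),
          education_years = round(pmin(20, pmax(
            8, stats::rnorm(1, g$education_mean, g$education_sd)))))
        transcripts[[length(transcripts) + 1L]] <- parse_transcript(list(
          participant_id = pid, group = if (gname %in% c("SSD", "HC"))
            gname else "unknown",
          cohort = sample(c("cohort1", "cohort2"), 1L),
          metadata = meta, turns = turn_specs))
        tl <- .sample_tlc(g$tlc, p %in% elevated_ids)
        ratings[[length(ratings) + 1L]] <- data.frame(
          participant_id = pid, t(stats::setNames(tl$items, paste0("tlc_item_", 1:18))),
          tlc_global = tl$global, tlc_total = tlc_total(tl$items),
          stringsAsFactors = FALSE)
      }
    }
    attr(transcripts, "group_of") <- vapply(transcripts, function(tr)
      sub("[0-9]+$", "", tr$participant_id), "")
    list(transcripts = transcripts, ratings = do.call(rbind, ratings),
         config = config)
  })
}

#' Write a corpus to disk in the package schema
#'
#' One JSON transcript per participant plus `ratings.csv`.
#'
#' @param corpus Output of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in corpus$transcripts)
    serialize_transcript(tr, file.path(dir, paste0(tr$participant_id, ".json")))
  utils::write.csv(corpus$ratings, file.path(dir, "ratings.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Orthonormal topic space for the toy embedding backend
#'
#' Topics A and B map to the first two axes of an identity basis; every
#' lexicon word is assigned to exactly one topic.
#'
#' @param dim Embedding dimension (>= 2), default 16.
#' @return List with `basis` (2 x dim, orthonormal rows), `assignment`
#'   (named topic vector over the lexicon), `dim`.
#' @export
topic_space <- function(dim = 16L) {
  stopifnot(dim >= 2L)
  lex <- builtin_lexicon()
  basis <- diag(1, nrow = 2L, ncol = dim)
  rownames(basis) <- c("A", "B")
  list(basis = basis, assignment = stats::setNames(lex$topic, lex$word),
       dim = as.integer(dim))
}

#' Seeded deterministic toy embedding backend
#'
#' `embed_words` maps each word to its topic's basis vector plus small
#' per-word jitter derived from a hash of the word and the backend seed
#' (jitter 0 gives an exact basis lookup). Out-of-vocabulary words get a
#' deterministic hash-derived unit vector and are logged once per word.
#' `nsp(s1, s2)` is a calibrated decreasing function of the cosine distance
#' between the two sentences' mean vectors, `exp(-3 d)`, so same-topic
#' sentence pairs score near 1 and orthogonal-topic pairs near 0.05.
#'
#' The default jitter (0.15) makes sentence embeddings scatter around their
#' topic direction, so prompt-response distances have a realistic nonzero
#' baseline instead of collapsing to 0 for on-topic replies.
#'
#' @param space A [topic_space()].
#' @param seed Integer seed for the per-word jitter.
#' @param jitter Jitter magnitude, default 0.15.
#' @return An embedding backend: list with `name`, `dim`, `embed_words`,
#'   `nsp`.
#' @export
toy_backend <- function(space = topic_space(), seed = 1L, jitter = 0.15) {
  cache <- new.env(parent = emptyenv())
  embed_one <- function(word) {
    w <- tolower(word)
    if (!is.null(cache[[w]])) return(cache[[w]])
    topic <- space$assignment[w]
    h <- (.string_hash(w) + as.integer(seed) * 7919L) %% 2147483647L
    noise <- with_seed(h, stats::rnorm(space$dim))
    v <- if (is.na(topic)) {
      message("toy backend: out-of-vocabulary word '", w,
              "'; using fallback vector")
      noise / sqrt(sum(noise^2))
    } else {
      space$basis[topic, ] + jitter * noise
    }
    cache[[w]] <- v
    v
  }
  embed_words <- function(words) {
    if (!length(words)) stop("no words to embed")
    t(vapply(words, embed_one, numeric(space$dim)))
  }
  nsp <- function(words1, words2) {
    m1 <- colMeans(embed_words(words1))
    m2 <- colMeans(embed_words(words2))
    d <- .embedding_distance(m1, m2, "cosine")
    exp(-3 * d)
  }
  list(name = "toy", dim = space$dim, embed_words = embed_words, nsp = nsp)
}
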