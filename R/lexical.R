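# Word-level group comparison: log-odds ratios regularized by an informative
# Dirichlet prior, plus per-participant disfluency and pronoun-class rates.

PSEUDO_WORDS <- c(first_sg = "<PRON_1SG>", first_pl = "<PRON_1PL>",
                  second = "<PRON_2>", third = "<PRON_3>",
                  incomplete = "<INCOMPLETE>")

# Vocabulary entries contributed by one transcript's participant speech:
# lower-cased words and fillers, pronoun-class pseudo-words in addition to
# the individual pronoun forms, and all incomplete fragments pooled into a
# single <INCOMPLETE> pseudo-word.
.vocab_items <- function(transcript) {
  toks <- participant_tokens(transcript)
  toks <- toks[!toks$kind %in% c("laughter", "redaction"), , drop = FALSE]
  items <- character()
  is_word <- toks$kind %in% c("word", "filler_um", "filler_uh")
  items <- c(items, tolower(toks$text[is_word]))
  items <- c(items, rep(PSEUDO_WORDS[["incomplete"]],
                        sum(toks$kind == "incomplete")))
  pron <- toks$pronoun_class[toks$pronoun_class != "none"]
  items <- c(items, unname(PSEUDO_WORDS[pron]))
  items
}

#' Accumulate per-group word counts
#'
#' Counts participant tokens only. Pronoun tokens are pooled into class
#' pseudo-words (`<PRON_1SG>` etc.) in addition to their individual surface
#' forms, and all incomplete-word fragments are pooled into `<INCOMPLETE>`.
#' The vocabulary is the union over both groups; a word absent from one group
#' gets a zero count there. Totals `n_a`, `n_b` are the analyzable participant
#' token counts (words + fillers + incomplete fragments).
#'
#' @param transcripts List of `speech_transcript` objects.
#' @param group_labels Character/factor of length `length(transcripts)` with
#'   exactly two levels; the first level becomes group A.
#' @return A `group_counts` object: list with `vocabulary`, `counts_a`,
#'   `counts_b`, `n_a`, `n_b`, `groups`.
#' @export
accumulate_counts <- function(transcripts, group_labels) {
  stopifnot(length(transcripts) == length(group_labels))
  # first label encountered defines group A (the positive-z side)
  f <- if (is.factor(group_labels)) group_labels else
    factor(group_labels, levels = unique(group_labels))
  if (nlevels(f) != 2L) stop("group_labels must have exactly two levels")
  if (any(table(f) == 0L)) stop("each group needs at least one transcript")
  items_a <- unlist(lapply(transcripts[f == levels(f)[1]], .vocab_items))
  items_b <- unlist(lapply(transcripts[f == levels(f)[2]], .vocab_items))
  vocab <- sort(unique(c(items_a, items_b)))
  counts_a <- table(factor(items_a, levels = vocab))
  counts_b <- table(factor(items_b, levels = vocab))
  n_a <- sum(vapply(transcripts[f == levels(f)[1]],
                    participant_token_total, 0L))
  n_b <- sum(vapply(transcripts[f == levels(f)[2]],
                    participant_token_total, 0L))
  structure(list(vocabulary = vocab,
                 counts_a = as.integer(counts_a),
                 counts_b = as.integer(counts_b),
                 n_a = n_a, n_b = n_b, groups = levels(f)),
            class = "group_counts")
}

#' Weighted log-odds with an informative Dirichlet prior
#'
#' For each word w with counts \eqn{y_a, y_b} in groups of \eqn{n_a, n_b}
#' tokens, the prior pseudo-count is \eqn{\alpha_w = \alpha_0 p_w} where
#' \eqn{p_w} is the word's relative frequency in the pooled corpus, so the
#' prior encodes the expected frequency of each word in a random text and
#' shrinks common words toward zero. The statistic is
#' \deqn{\delta_w = \log\frac{y_a+\alpha_w}{n_a+\alpha_0-y_a-\alpha_w}
#'              - \log\frac{y_b+\alpha_w}{n_b+\alpha_0-y_b-\alpha_w}}
#' with variance \eqn{\sigma^2_w = 1/(y_a+\alpha_w) + 1/(y_b+\alpha_w)} and
#' z-score \eqn{z_w = \delta_w/\sigma_w}. Positive z marks words
#' over-represented in group A.
#'
#' @param gc A `group_counts` object.
#' @param alpha0 Total prior mass (pseudo-token count), > 0. Default 100.
#' @param min_count Minimum pooled count for a word to be reported; set 0 to
#'   keep everything. Default 5.
#' @return data.frame sorted by `z` descending with columns `word`,
#'   `count_a`, `count_b`, `alpha`, `delta`, `variance`, `z`.
#' @export
weighted_log_odds <- function(gc, alpha0 = 100, min_count = 5) {
  stopifnot(inherits(gc, "group_counts"))
  if (!is.numeric(alpha0) || length(alpha0) != 1L || alpha0 <= 0)
    stop("alpha0 must be a positive number")
  y_a <- gc$counts_a; y_b <- gc$counts_b
  pooled <- y_a + y_b
  p_w <- pooled / (gc$n_a + gc$n_b)
  alpha_w <- alpha0 * p_w
  delta <- log((y_a + alpha_w) / (gc$n_a + alpha0 - y_a - alpha_w)) -
           log((y_b + alpha_w) / (gc$n_b + alpha0 - y_b - alpha_w))
  variance <- 1 / (y_a + alpha_w) + 1 / (y_b + alpha_w)
  z <- delta / sqrt(variance)
  out <- data.frame(word = gc$vocabulary, count_a = y_a, count_b = y_b,
                    alpha = alpha_w, delta = delta, variance = variance,
                    z = z, stringsAsFactors = FALSE)
  out <- out[pooled >= min_count, , drop = FALSE]
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-participant lexical and disfluency rates
#'
#' Rates are per 100 analyzable participant tokens (words + fillers +
#' incomplete fragments; laughter and redactions excluded from the
#' denominator). `uh_um_ratio` is uh/(uh+um), `NA` when the participant
#' produced no filled pause at all.
#'
#' @param transcript A `speech_transcript` with participant speech.
#' @return One-row data.frame: `participant_id`, `token_total`,
#'   `incomplete_rate`, `laughter_rate`, `um_rate`, `uh_rate`,
#'   `pron_first_sg_rate`, `pron_first_pl_rate`, `pron_second_rate`,
#'   `pron_third_rate`, `uh_um_ratio`, `incomplete_count`.
#' @export
lexical_profile <- function(transcript) {
  toks <- participant_tokens(transcript)
  denom <- sum(!toks$kind %in% c("laughter", "redaction"))
  if (denom == 0L)
    stop(sprintf("participant %s has no analyzable tokens",
                 transcript$participant_id))
  n_um <- sum(toks$kind == "filler_um")
  n_uh <- sum(toks$kind == "filler_uh")
  n_inc <- sum(toks$kind == "incomplete")
  rate <- function(count) 100 * count / denom
  data.frame(
    participant_id = transcript$participant_id,
    token_total = denom,
    incomplete_count = n_inc,
    incomplete_rate = rate(n_inc),
    laughter_rate = rate(sum(toks$kind == "laughter")),
    um_rate = rate(n_um),
    uh_rate = rate(n_uh),
    pron_first_sg_rate = rate(sum(toks$pronoun_class == "first_sg")),
    pron_first_pl_rate = rate(sum(toks$pronoun_class == "first_pl")),
    pron_second_rate = rate(sum(toks$pronoun_class == "second")),
    pron_third_rate = rate(sum(toks$pronoun_class == "third")),
    uh_um_ratio = if (n_um + n_uh == 0L) NA_real_ else n_uh / (n_uh + n_um),
    stringsAsFactors = FALSE
  )
}

#' Per-participant word-usage score against a ranked word table
#'
#' Aggregates a participant's usage of group-discriminating words into one
#' scalar: the sum over scored words of `z_w` times the participant's
#' per-100-word usage rate of w (pseudo-words included). This is the
#' word-level summary exported to the classifier feature matrix.
#'
#' @param transcript A `speech_transcript`.
#' @param word_scores Output of [weighted_log_odds()].
#' @return Numeric scalar.
#' @export
word_usage_score <- function(transcript, word_scores) {
  items <- .vocab_items(transcript)
  denom <- participant_token_total(transcript)
  if (denom == 0L) return(NA_real_)
  counts <- table(factor(items, levels = word_scores$word))
  sum(word_scores$z * 100 * as.numeric(counts) / denom)
}
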