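# Sentence-level coherence: next-sentence probabilities aggregated per
# participant, and prompt-anchored embedding-distance trajectories.
#
# Embedding backends are plug-ins: a list with
#   embed_words(words)  -> one row per word, fixed dimension
#   nsp(words1, words2) -> next-sentence probability in [0, 1]
# both deterministic for fixed inputs. The shipped backend is the seeded
# toy embedder from the synthetic-data module ([toy_backend()]); a
# pretrained bidirectional transformer can be substituted behind the same
# contract without touching any of the functions below.

# words that carry embeddable content: completed words and filled pauses;
# laughter marks, redaction placeholders and abandoned fragments do not
.embeddable_words <- function(sentence) {
  toks <- sentence$tokens
  toks$text[!toks$kind %in% c("laughter", "redaction", "incomplete")]
}

#' Extract (previous sentence, participant sentence) pairs
#'
#' Every participant sentence with an immediately preceding sentence (from
#' either speaker) yields one pair, in spoken order. A transcript opening
#' with participant speech contributes no pair for that first sentence.
#'
#' @param transcript A `speech_transcript`.
#' @return List of pairs `list(first = <sentence>, second = <sentence>)`.
#' @export
sentence_pairs <- function(transcript) {
  sents <- transcript_sentences(transcript)
  if (length(sents) < 2L) return(list())
  pairs <- list()
  for (i in 2:length(sents)) {
    if (sents[[i]]$speaker == "participant")
      pairs <- c(pairs, list(list(first = sents[[i - 1L]],
                                  second = sents[[i]])))
  }
  pairs
}

#' Mean next-sentence probability for a participant
#'
#' Scores each pair with the backend and averages. With `min_words`, pairs
#' whose second (participant) sentence has fewer words are dropped before
#' averaging; with `length_weighting`, probabilities are weighted by the
#' second sentence's length normalized by the mean retained length
#' (weighted mean = sum(w*p)/sum(w)).
#'
#' @param pairs Output of [sentence_pairs()].
#' @param backend Embedding backend providing `nsp`.
#' @param min_words Minimum second-sentence word count, default 0 (keep all).
#' @param length_weighting Logical, default `FALSE`.
#' @return List: `pair_probabilities` (data.frame `pair`, `n_words`,
#'   `probability`, `retained`), `mean_nsp` (`NA` if every pair is filtered
#'   out), `min_words`, `length_weighting`.
#' @export
mean_nsp <- function(pairs, backend, min_words = 0, length_weighting = FALSE) {
  if (!length(pairs))
    return(list(pair_probabilities = data.frame(), mean_nsp = NA_real_,
                min_words = min_words, length_weighting = length_weighting))
  probs <- vapply(pairs, function(p)
    backend$nsp(.embeddable_words(p$first), .embeddable_words(p$second)), 0)
  lens <- vapply(pairs, function(p) length(.embeddable_words(p$second)), 0L)
  retained <- lens >= min_words
  df <- data.frame(pair = seq_along(pairs), n_words = lens,
                   probability = probs, retained = retained)
  if (!any(retained)) {
    warning("all sentence pairs filtered out; mean NSP is missing")
    m <- NA_real_
  } else if (length_weighting) {
    w <- lens[retained] / mean(lens[retained])
    m <- sum(w * probs[retained]) / sum(w)
  } else {
    m <- mean(probs[retained])
  }
  list(pair_probabilities = df, mean_nsp = m,
       min_words = min_words, length_weighting = length_weighting)
}

#' Embed an interviewer turn as the mean of its word vectors
#'
#' @param turn A turn object (interviewer prompt).
#' @param backend Embedding backend providing `embed_words`.
#' @return Numeric vector (the arithmetic mean over all word vectors across
#'   all sentences of the turn).
#' @export
prompt_embedding <- function(turn, backend) {
  words <- unlist(lapply(turn$sentences, .embeddable_words))
  if (!length(words)) stop("turn has no embeddable tokens")
  colMeans(backend$embed_words(words))
}

.embedding_distance <- function(x, y, metric) {
  switch(metric,
    cosine = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 || ny == 0) return(NA_real_)
      d <- 1 - sum(x * y) / (nx * ny)
      max(d, 0)  # guard tiny negative rounding
    },
    euclidean = sqrt(sum((x - y)^2)),
    mean_abs = mean(abs(x - y)),
    stop("unknown metric: ", metric))
}

#' Embedding-distance trajectory of one exchange
#'
#' Embeds the interviewer prompt turn and each participant response sentence
#' (mean-pooled word vectors) and returns one point per response: its
#' position j = 1..k (distance from the prompt in sentences) and its
#' embedding distance from the prompt. Sentences with no embeddable tokens
#' (e.g. only redactions) are skipped with a message.
#'
#' @param exchange One element of [extract_exchanges()] output.
#' @param backend Embedding backend.
#' @param metric `"cosine"` (default), `"euclidean"` or `"mean_abs"`.
#' @return data.frame with columns `position`, `distance`.
#' @export
trajectory_points <- function(exchange, backend,
                              metric = c("cosine", "euclidean", "mean_abs")) {
  metric <- match.arg(metric)
  e_i <- prompt_embedding(exchange$prompt, backend)
  pos <- integer(); dist <- numeric()
  for (s in exchange$responses) {
    words <- .embeddable_words(s)
    if (!length(words)) {
      message(sprintf("skipping unembeddable response sentence at position %d",
                      s$index_in_turn))
      next
    }
    e_sj <- colMeans(backend$embed_words(words))
    pos <- c(pos, s$index_in_turn)
    dist <- c(dist, .embedding_distance(e_i, e_sj, metric))
  }
  data.frame(position = pos, distance = dist)
}

#' Pooled trajectory points for a set of transcripts
#'
#' @param transcripts List of `speech_transcript` objects.
#' @param backend Embedding backend.
#' @param metric Distance metric, as [trajectory_points()].
#' @return data.frame `participant_id`, `exchange`, `position`, `distance`.
#' @export
corpus_trajectory_points <- function(transcripts, backend, metric = "cosine") {
  out <- list()
  for (tr in transcripts) {
    exchanges <- extract_exchanges(tr)
    for (e in seq_along(exchanges)) {
      pts <- trajectory_points(exchanges[[e]], backend, metric)
      if (nrow(pts))
        out[[length(out) + 1L]] <- cbind(
          data.frame(participant_id = tr$participant_id, exchange = e),
          pts)
    }
  }
  if (!length(out))
    return(data.frame(participant_id = character(), exchange = integer(),
                      position = integer(), distance = numeric()))
  do.call(rbind, out)
}

#' Ordinary least squares fit of distance on position
#'
#' Fits `distance ~ position` to pooled trajectory points and returns the
#' intercept and slope with their 95% confidence intervals from the standard
#' OLS standard errors and t critical value.
#'
#' @param points data.frame with `position` and `distance` columns (pooled
#'   across a group's exchanges, or one participant's).
#' @return A `trajectory_fit`: list with `intercept`, `slope`,
#'   `ci95_intercept`, `ci95_slope`, `n_points`.
#' @export
fit_trajectory <- function(points) {
  if (nrow(points) < 3L) stop("need at least 3 points to fit a trajectory")
  if (length(unique(points$position)) < 2L)
    stop("all positions identical; slope undefined")
  fit <- stats::lm(distance ~ position, data = points)
  ci <- stats::confint(fit, level = 0.95)
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    ci95_intercept = unname(ci["(Intercept)", ]),
    ci95_slope = unname(ci["position", ]),
    n_points = nrow(points)
  ), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("trajectory fit (n=%d): intercept %.4f [%.4f, %.4f], slope %.2e [%.2e, %.2e]\n",
              x$n_points, x$intercept, x$ci95_intercept[1], x$ci95_intercept[2],
              x$slope, x$ci95_slope[1], x$ci95_slope[2]))
  invisible(x)
}
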