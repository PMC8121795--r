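---
title: "Methods: three-level linguistic phenotyping of interview speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-level linguistic phenotyping of interview speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented by `speechmarkers`, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the method description left the design open. It
states no empirical result that the package's tests do not themselves
compute.

## The data model

The unit of analysis is a diarized transcript: ordered turns labelled
interviewer (`I`) or participant (`P`), each split into sentences **only at
terminal punctuation placed by a human transcriber** (`.?!`). This matters:
automatic sentence splitters segment disfluent speech at incomplete, filler
and repeated words, and because disfluencies are more frequent in clinical
groups, the resulting fragment boundaries depress next-sentence
probabilities differentially and can manufacture a spurious group effect.
All sentence-level analyses therefore consume transcriber punctuation and
never re-split.

Tokens are whitespace-delimited with surface case preserved and
case-insensitive matching, and carry an annotation kind:

* `filler_um` / `filler_uh` — the filled pauses "um" and "uh";
* `incomplete` — a word begun but abandoned, marked by a trailing ASCII
  hyphen after at least one letter (`"sto-"`); the printed example
  "I sto- stopped at the store" is the canonical form;
* `laughter` — the `[laughter]` mark (no format is standard for non-verbal
  vocalizations; this one is the package's convention);
* `redaction` — the privacy placeholders `[name]` and `[date]`;
* `word` — everything else.

Personal pronouns are additionally classed into first-person singular
(*I, me, my, mine, myself*), first-person plural, second and third person,
using fixed lexicons (the method description pools "all pronouns of the same
type" without listing forms; the lexicons are frozen in
`pronoun_lexicon()`).

**Rate denominator.** All per-100-word rates divide by the participant's
analyzable tokens: words + filled pauses + incomplete fragments, excluding
laughter marks and redaction placeholders. Fillers count as words because
they are classed as interjections in the POS analysis; laughter and
redactions are annotations about the signal, not words.

**Dialogue exchanges** anchor the trajectory analysis: one interviewer
prompt turn plus every participant sentence before the interviewer speaks
again, positions 1..k. Adjacent same-speaker segments are merged at parse
time (how interviewer back-channels were segmented is not specified
anywhere; merging is this package's decision). Participant speech before
the first prompt belongs to no exchange — exchanges are prompt-anchored by
definition — but still counts toward lexical and POS statistics.

## Word level: Dirichlet-weighted log-odds

For word $w$ with group counts $y_{aw}, y_{bw}$ and group totals $n_a, n_b$:

$$\delta_w=\log\frac{y_{aw}+\alpha_w}{n_a+\alpha_0-y_{aw}-\alpha_w}
-\log\frac{y_{bw}+\alpha_w}{n_b+\alpha_0-y_{bw}-\alpha_w},\qquad
\sigma^2_w=\frac{1}{y_{aw}+\alpha_w}+\frac{1}{y_{bw}+\alpha_w},\qquad
z_w=\delta_w/\sigma_w.$$

The informative Dirichlet prior allocates pseudo-counts
$\alpha_w=\alpha_0 p_w$ proportional to the expected frequency $p_w$ of the
word in a random text, so frequent words need a proportionally larger
imbalance to stand out.

* **Background distribution**: no external corpus is part of the method
  description, so $p_w$ is estimated from the pooled study corpus itself —
  the only estimate available that covers the pseudo-words below.
* **$\alpha_0$ = 100** by default (configurable). The original
  informative-prior literature leaves the mass to the analyst; 100
  pseudo-tokens against corpora of tens of thousands of tokens regularizes
  rare words without flattening genuine effects.
* **Pseudo-word pooling**: pronoun classes and incomplete words are pooled
  into `<PRON_1SG>`-style pseudo-words *in addition to* the individual
  surface forms, because results are reported at both granularities.
  A consequence is that pooled counts exceed token totals slightly; the
  statistic is computed per word, so this affects nothing but the
  interpretation of the vocabulary as a partition.
* **Reporting filter**: words with pooled count < 5 are omitted from ranked
  output (configurable). No threshold is stated in the method description;
  without one, hapax words dominate the rank extremes unstably.

Verification: the z-scores are checked against an independent 50-digit
`mpmath` evaluation of the same formula on 200 random count configurations
(agreement < 1e-9), and antisymmetry under group exchange is exact.

## POS level

Ten coarse categories (adverb, determiner, adjective, pronoun, preposition,
particle, conjunction, noun, interjection, verb) are counted per 100
analyzable tokens. The tagger is a backend contract — one closed-set label
per token, deterministic for fixed input. Two mapping decisions are the
package's own (the reported table lists ten categories without its mapping):
auxiliaries count as verbs, proper nouns as nouns, coordinating and
subordinating conjunctions merge, adpositions are prepositions; numerals,
symbols and unknowns are `OTHER` — excluded from every numerator but kept in
the denominator. Filled pauses are always interjections; incomplete
fragments, redactions and laughter are always `OTHER`, whatever the backend
says.

The shipped backend is a deterministic closed-lexicon tagger over the
generator's 611-form vocabulary, so tests need no model download. On real
data one would wrap a pretrained tagger in the same contract.

Group comparisons use ANCOVA: a linear model of each rate on group plus age,
sex, race, education years and study cohort (categoricals one-hot with
first-observed reference level; the group p-value is the adjusted t-test,
equivalent to the two-level ANCOVA F). Cohen's *d* is reported from **raw**
group means and pooled SD even when the p-value is adjusted, matching the
convention of printing raw descriptives next to adjusted tests; whether the
published effect sizes were adjusted is not stated, and this choice is
documented rather than guessed at.

## Sentence level

**Next-sentence probability (NSP).** Every participant sentence with an
immediately preceding sentence (either speaker) forms a pair; a backend
scores each pair in [0,1]; the participant's score is the plain mean.
Options mirror the published sensitivity checks: drop pairs whose second
sentence has fewer than `min_words` words (5 in the published check), or
weight by sentence length normalized by the mean retained length
(`sum(w·p)/sum(w)`). Both default off.

**Tangentiality trajectories.** The prompt turn is embedded as the
arithmetic mean of all its word vectors; each response sentence likewise;
the trajectory point at position $j$ is the distance between the two.
Design choices:

* **Distance metric**: the method description says only "mean difference"
  between embeddings, which does not identify a metric. Cosine distance is
  the default — the reported magnitudes (~0.25 on transformer embeddings)
  are consistent with cosine on mean-pooled vectors, and it is
  scale-invariant, which matters when sentence lengths differ by group.
  Euclidean and mean absolute componentwise difference are selectable.
* **Pooling**: mean over word vectors, no special-token pooling, mirroring
  the stated prompt-embedding construction; whole prompt turns are embedded
  (no truncation — whether multi-sentence prompts were truncated is
  unstated).
* **Unembeddable content**: laughter, redactions and incomplete fragments
  carry no stable semantics and are excluded from embedding; a sentence
  with nothing left is skipped and logged.
* **Fitting**: OLS of distance on position, pooled across a group's
  exchanges (matching group-trajectory figures), with per-participant fits
  exported as classifier features. 95% CIs use the standard OLS standard
  errors and t critical values. Points at every position are kept; a
  plotted position range is a display choice, not a filter.

## Discrimination

Gaussian naive Bayes on standardized features, class priors from
training-fold frequencies, per-class variances floored at `1e-9` times the
largest feature variance. Cross-validation is leave-one-out by default
(five-fold stratified with a fixed seed as confirmation). Inside every
training fold — never on the test fold — missing values are imputed by the
fold mean and features z-scored by fold statistics; a constant feature
becomes all zeros. Accuracy thresholds the out-of-fold probability at 0.5
(unstated in the method description); AUC is the Mann–Whitney statistic over
pooled out-of-fold probabilities, the only coherent aggregation under
leave-one-out, applied to k-fold as well for uniformity.

Feature sets: `clinical` = 18 rating items + global + total; `nlp` =
word-usage score, mean NSP, per-participant trajectory intercept and slope,
ten POS rates, incomplete-word count; `combined` = union; optionally
education years appended. Which per-word log-odds summaries entered the
published classifier is not stated; this package exports one scalar per
participant — the sum over scored words of $z_w$ times the participant's
per-100-word usage of $w$ — and documents it as a reconstruction.

## The synthetic generator: what a green test establishes

`generate_corpus()` emulates two-group interview corpora: topic-A
interviewer prompts; bag-of-words participant sentences over a closed
611-form lexicon with hand-assigned POS and topic labels; per-group POS
category mixes (the defaults are the published per-100-word group means,
renormalized); pronoun-class mixes; uh:um mixes (0.8 vs 0.3 in the
effect preset); per-word incomplete-fragment probabilities (0.03 vs 0.002);
laughter rates; zero-inflated rating items (mostly zero in both groups,
with 4 elevated participants on the SSD-like side — the modal global score
is zero, as in the population being emulated); and group-specific mean
sentence lengths (14.4 vs 17.5 words) and education distributions.
Sizes default to 15 participants per group producing roughly 1500–1900
words each, matching the recording lengths being emulated.

Topic drift models tangentiality: response sentence $j$ samples content
words from mixture $(1-m_j)A + m_jB$ with
$m_j = \min(\text{drift\_start} + \text{drift\_slope}\cdot j,\,1)$.
The effect preset uses `drift_start = 0.12`, `drift_slope = 0.015` for the
SSD-like group and zero for the other. The level term exists because the
published pattern is *level-dominant*: responses begin farther off topic
(intercept difference 0.013) while the slope is small (6.6e-4). A
slope-only construction cannot reproduce that pattern robustly — with
substantial drift per sentence the distance-position curve becomes convex
and the fitted intercept extrapolates *below* the position-1 level, so the
group ordering of intercepts would hinge on noise. With a dominant level
term and a gentle slope, the SSD-like group's fitted slope CI excludes zero,
the control group's covers it, and the intercept ordering is stable across
seeds.

The toy embedding backend maps each lexicon word to its topic's basis
vector plus seeded per-word jitter (default 0.15, giving trajectories a
realistic nonzero baseline), with a deterministic hash-derived unit vector
for out-of-vocabulary words; NSP is `exp(-3·cosine distance)` between
sentence means, so same-topic pairs score near 1.

What the generator does **not** emulate: syntax (sentences are bags of
words), discourse structure, annotator disagreement, recognition errors,
medication effects, and real lexical diversity. A green recovery test
therefore establishes that the *pipeline* recovers known injected effects in
the right direction with calibrated error rates — not that the effects
generalize to real clinical speech, and not the published numeric values,
whose corpora are unavailable.

## Numerical and statistical conventions

* Quartiles for boxplot outlier fences use linear interpolation (R type 7);
  "the standard boxplot method" is ambiguous across software, so the
  convention is fixed and documented.
* Wilcoxon rank-sum: exact enumeration when the smaller sample has ≤ 8
  observations and the pooled data are tie-free, tie-corrected normal
  approximation otherwise; identical samples give p = 1.
* Shapiro–Wilk decides parametric vs rank tests at p < 0.05; a constant
  vector (test undefined) is reported non-normal.
* A constant outcome in the covariate-adjusted linear model reports
  coefficient 0 and p = 1; a rank-deficient design is an error naming the
  collinear columns; zero-variance covariates are dropped with a message.
* No multiple-comparison correction anywhere, matching the exploratory
  design being reproduced.
* Type-I-error calibration of the battery (ten POS ANCOVAs + the NSP
  model) is checked over 500 null-generator replicates at α = 0.05 against
  a [0.03, 0.07] per-feature band, with corpora scaled down in *size only*
  to fit the time budget. Note the band spans about ±2 Monte-Carlo standard
  errors of a rate estimated from 500 replicates, so across an 11-feature
  battery an occasional single-feature excursion is expected even under
  perfect calibration. The clinician-rating rank-sum test is excluded from
  the calibration band:
  under a zero-inflated null its p-value distribution is discrete and
  conservative — a property of rank tests on ties, not a defect to
  calibrate away.
* All randomness is seed-controlled; generation restores the caller's RNG
  state.

## Known limitations

* The rule tagger and toy embedder are exact only over the closed lexicon;
  real-data use requires wrapping pretrained backends (kept strictly
  optional so the test suite is hermetic).
* The word-score classifier feature is a reconstruction (see above).
* The trajectory intercept compares groups descriptively; no formal
  intercept-difference test is implemented because the published comparison
  relies on CI non-overlap.
* Transcriber-XML support covers speaker-segmented `<Turn>` dialects only;
  unrecognized markup is skipped with a warning, not parsed.
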