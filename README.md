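# speechmarkers

Linguistic phenotyping of diarized clinical interview speech.

Speech disturbance is a hallmark of schizophrenia spectrum disorders (SSD),
but clinician rating scales miss the subclinical end of the phenotype.
`speechmarkers` quantifies language disturbance directly from
speaker-labelled, verbatim interview transcripts on three levels, and tests
whether those measures separate groups better than clinical ratings do:

1. **Individual words** — group word-usage comparison with log-odds ratios
   weighted by an informative Dirichlet prior. For word *w* with counts
   *y<sub>aw</sub>*, *y<sub>bw</sub>* in groups of *n<sub>a</sub>*,
   *n<sub>b</sub>* tokens and prior mass α₀ spread as
   α<sub>w</sub> = α₀·p<sub>w</sub> (p<sub>w</sub> the pooled relative
   frequency):

   δ<sub>w</sub> = log[(y<sub>aw</sub>+α<sub>w</sub>)/(n<sub>a</sub>+α₀−y<sub>aw</sub>−α<sub>w</sub>)] −
   log[(y<sub>bw</sub>+α<sub>w</sub>)/(n<sub>b</sub>+α₀−y<sub>bw</sub>−α<sub>w</sub>)],
   σ²<sub>w</sub> = 1/(y<sub>aw</sub>+α<sub>w</sub>) + 1/(y<sub>bw</sub>+α<sub>w</sub>),
   z<sub>w</sub> = δ<sub>w</sub>/σ<sub>w</sub>.

   Pronoun classes (first-person singular/plural, second, third) and
   incomplete words ("I sto- stopped...") are pooled into pseudo-words in
   addition to the individual forms; filled pauses ("um", "uh") are ordinary
   words.
2. **Parts of speech** — ten coarse POS rates per 100 words through a
   pluggable tagger backend, compared between groups by ANCOVA with
   demographic covariates (age, sex, race, education, cohort) and raw
   Cohen's *d*.
3. **Sentences** — a pluggable embedding backend supplies (a) next-sentence
   probabilities for every (previous sentence, participant sentence) pair,
   averaged per participant, and (b) *tangentiality trajectories*: the
   embedding distance between an interviewer prompt (mean word vector of the
   whole turn) and each successive participant response sentence, regressed
   on the sentence's distance-from-prompt position (OLS intercept/slope with
   95% CIs).

A Gaussian naive Bayes harness with leave-one-out (or stratified k-fold)
cross-validation compares feature sets: clinical ratings only (18
thought/language/communication items + global + total), NLP features only,
and their union.

Because the clinical recordings such methods are developed on are not
shareable, the package ships a deterministic synthetic corpus generator
(diarized transcripts with controllable pronoun/POS/filled-pause/
incomplete-word/topic-drift effects and zero-inflated ratings) and a seeded
toy embedding backend, so the entire pipeline is testable offline. A
pretrained transformer can be plugged in behind the same backend contract
for real data.

## Worked example

```r
library(speechmarkers)
corpus <- generate_corpus(ssd_hc_preset(n_per_group = c(15, 15), seed = 1))
report <- run_study(corpus, seed = 1)
print(report)
```

```
== study report ==
POS comparison (per 100 words):
       category mean_a mean_b  p_value cohens_d
1        adverb   9.42  11.53 5.26e-05   -2.251
2    determiner   7.13   8.22 5.95e-04   -1.773
3     adjective   6.95   7.80 4.25e-03   -1.120
4       pronoun  14.44  12.49 3.81e-04    1.762
5   preposition   8.70   9.55 1.75e-03   -0.882
6      particle   2.59   2.94 1.96e-01   -0.617
7   conjunction   4.89   5.65 3.93e-02   -1.147
8          noun  14.78  14.63 3.82e-01    0.130
9  interjection   7.00   6.48 1.40e-01    0.692
10         verb  21.18  20.53 2.60e-01    0.452

Top group-A-associated words:
          word count_a count_b     z
1 <INCOMPLETE>     707      55 19.54
2   <PRON_1SG>    1925    1133 19.10
3           uh     750     295 15.97
4           me     376     213  8.40
5       myself     382     219  8.36

Trajectory fits:
  SSD: trajectory fit (n=1633): intercept 0.0935 [0.0844, 0.1026], slope 4.60e-03 [2.61e-03, 6.59e-03]
  HC: trajectory fit (n=1609): intercept 0.0759 [0.0702, 0.0816], slope 2.14e-04 [-1.03e-03, 1.46e-03]

Discrimination:
  naive Bayes [clinical, loo]: AUC = 0.551, accuracy = 66.7%
  naive Bayes [nlp, loo]: AUC = 1.000, accuracy = 100.0%
  naive Bayes [combined, loo]: AUC = 0.933, accuracy = 93.3%
```

Reading the output: group A (the SSD-like group) uses fewer adverbs,
determiners and adjectives but more pronouns per 100 words (ANCOVA p-values
adjusted for demographics); its most characteristic "words" are the pooled
incomplete-word and first-person-singular pseudo-tokens and the filler
"uh"; its responses start farther from the interviewer's prompt (higher
intercept) and wander increasingly off topic (slope CI excluding zero,
unlike group B); and the linguistic features separate the groups essentially
perfectly under leave-one-out cross-validation while the deliberately
near-degenerate (mostly-zero) clinical ratings do not.

## Command line

```sh
speechmarkers simulate --preset ssd_hc --seed 1 --n 15 --out-dir corpus/
speechmarkers run-all  --in-dir corpus/ --seed 1 --out-dir results/
```

(the script installs under `<library>/speechmarkers/exec/speechmarkers`;
subcommands `featurize`, `analyze`, `classify`, `report` write the
corresponding slice of the run-all output).

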