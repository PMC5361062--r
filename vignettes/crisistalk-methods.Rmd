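---
title: "Methods: discourse analysis of crisis counseling conversations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discourse analysis of crisis counseling conversations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crisistalk` implements a family of quantitative discourse measures for
two-party crisis counseling conversations — SMS-style exchanges between a
trained counselor and a person in distress (the texter), each conversation
optionally labeled with a binary outcome from the texter's post-conversation
survey ("feeling better" vs "same/worse"). Real corpora of this kind are
access-restricted, so the package pairs every measure with a synthetic-corpus
generator whose planted parameters make each measure's expected behavior a
known quantity. This vignette explains the models, the tunable parameters,
the numerical choices, and what the synthetic validation does and does not
establish.

## The corpus model

A conversation is an ordered list of messages, each with a role (`counselor`
or `texter`), raw text, and a deterministic token list (lowercase, split on
non-alphanumeric runs; digits kept). Corpora are stored as one JSON object
per line (`{conv_id, counselor_id, outcome?, issue?, messages: [{role,
text}]}`); `read_corpus()` / `write_corpus()` round-trip losslessly.

Counselor quality is defined behaviorally: a counselor is eligible when they
have strictly more than 15 labeled conversations of at least 30 messages
each, and eligible counselors are ranked by their labeled success rate. The
top and bottom blocks of the ranking form the *more successful* and *less
successful* groups. Ranking ties are broken by labeled-conversation count
and then id, so the split is deterministic. On corpora of desk scale the
group sizes are parameters (`top_n`, `bottom_n`); the defaults suit a corpus
with hundreds of counselors.

## The synthetic generator and its planted effects

`generator_config()` fixes every planted effect of the study corpus. The
defaults are the conditions used throughout the package's validation and
were chosen once, to be realistic for the domain at a size where every
analysis runs in seconds:

* **Size.** 10 counselors, 400 conversations assigned round-robin (40 per
  counselor — enough labeled conversations per counselor for the eligibility
  filter), lengths drawn from N(45, 8²) clipped to [30, 60] messages
  (text-counseling corpora report means near 43 messages per conversation).
  Roles alternate strictly, counselor first.
* **Stages.** A latent stage starts at 1 and advances by at most one after
  each message with per-stage probabilities (0.20, 0.12, 0.10, 0.15); the
  last stage absorbs. Each message is a bag of words: with probability
  `keyword_weight = 0.8` a token comes from the (stage, role) keyword list
  (10 synthetic keywords per cell, disjoint across stages), otherwise from a
  shared background. Word identifiers are lowercase alphanumeric so they
  survive tokenization unchanged.
* **Outcome and quality.** Counselor quality alternates 0.8 / 0.5; each
  conversation's outcome is Bernoulli(quality of its counselor).
* **Drift.** In chunk *c* of 5, each counselor token is replaced with a word
  from the outcome's drift lexicon with probability
  `drift_strength * (c-1)/4` (default maximum 0.25). Drift is zero in the
  first fifth and grows linearly, giving the language-divergence measure a
  monotone ground truth that starts at zero.
* **Coordination.** For each of eight stylistic marker categories, exhibit
  indicators follow a two-state chain across messages: a message exhibits
  the marker with probability `base = 0.2`, raised by `delta = 0.1` when the
  previous message exhibited it; exhibiting injects one marker word, drawn
  with Zipf weights over the category's list (function words are Zipfian in
  natural text; uniform injection would scatter mass over many rare,
  high-idf words and drown the TF-IDF measures in noise).
* **Counselor style.** Hedge words and check-question phrases are injected
  per counselor message with outcome-dependent probabilities (hedges 0.45 vs
  0.20; check questions 0.30 vs 0.10). These are the planted signals the
  outcome classifier must find.
* **Situation setter.** The first texter message is kept short; the second
  is a negative-binomial draw truncated at 10 tokens, plus
  `setter_length_effect = 4` tokens in positive conversations. The recorded
  ground-truth setter is recomputed from the final emitted tokens, since
  marker injection can occasionally push an earlier message over the
  threshold.
* **Psycholinguistic schedules.** Texter background tokens enter a category
  channel with probability `cat_rate = 0.3`; within it, tense, pronoun
  focus, and emotion words follow linear schedules over conversation fifths
  whose endpoints depend on the outcome (e.g. the future-word share rises
  from 0.15 to 0.45 in positive and 0.25 in negative conversations).

Everything is driven by one seed; the same `(config, seed)` yields a
byte-identical corpus.

**Isolation configs.** Channels interact: category words overlap the pronoun
and auxiliary-verb marker lexicons, and marker injections add pronouns that
dilute the pronoun-focus schedule. Validation experiments that quantify one
channel therefore switch the interfering channels off — the coordination
recovery experiment sets `cat_rate = 0` so marker exhibits are governed
solely by the planted chain; the perspective-schedule recovery disables
marker injection; the no-signal null for the divergence measure sets
`drift_strength = 0` *and* equalizes the style probabilities across
outcomes, since outcome-dependent hedging is itself a language–outcome
link. These are statements of each experiment's conditions, not tuning.

## Counselor adaptability (language divergence over time)

Each conversation is cut into five contiguous chunks of messages (earlier
chunks larger when the count is not divisible). For a counselor group,
outcome, and chunk, a term-frequency vector of counselor tokens is
accumulated with each conversation weighted by 1/(its counselor's
conversation count in that cell), so every counselor contributes equal mass;
the vector is multiplied by global inverse *conversation* frequencies
(`idf = ln(N/df)`, no smoothing — observed words always have `df ≥ 1`) and
L2-normalized. The adaptability curve is the cosine distance between the
positive and negative vectors per chunk. Confidence intervals resample
counselors with replacement (member bootstrap, default 1000 resamples);
`adaptability_null()` permutes outcome labels to give a no-signal band.

Numerical choices: cosine values within 1e-12 of 1 are snapped to 1 so
identical cells give distance exactly 0; empty cells raise an error naming
the chunk.

## Ambiguity, setter clustering, and templatedness

Ambiguity is operationalized as shortness of the texter's situation setter —
the first texter message with at least 10 tokens ("long" is not quantified
in the field; the threshold is a parameter). `ambiguity_outcome_table()`
bins setters by length and reports positive-outcome fractions with exact
binomial CIs; `counselor_texter_length_ratio()` measures how much more
counselors write in reply to short setters.

Near-identical setters are matched as bigram TF-IDF vectors, with nearest
neighbors within a cosine-distance threshold (default 0.4; the thresholds in
this literature are validated manually, so it is a parameter). Setters with
at least `min_neighbors = 10` neighbors seed dense clusters; overlapping
neighborhoods are merged by union, which makes the construction
order-invariant. **Idf convention:** this matching space uses the smoothed,
strictly positive idf `ln((1+N)/(1+df)) + 1`. With the unsmoothed
convention, a bigram present in every document gets weight 0 and identical
documents become zero vectors with undefined similarity — the smoothed form
keeps "identical texts are at distance 0" true, which is the property the
matching depends on. The divergence measure above keeps the plain
`ln(N/df)` convention; the two spaces serve different purposes and are
documented separately on purpose.

Counselor replies to clustered setters are classified by case-insensitive
regular-expression patterns into check questions ("sounds like", "it
seems", "i hear", …), suicide checks, thanks/affirmation, hedges, and
surprise (which additionally requires a leading interjection). The shipped
patterns are open word lists — the licensed category dictionaries used in
the psycholinguistics literature are not redistributable — and any YAML
lexicon of the same shape can be substituted. Templatedness counts, for
each reply, the other replies within the distance threshold; its inverse
proxies creativity. The default generator does not plant near-duplicate
openings, so cluster-based analyses are validated on constructed template
fixtures rather than on the synthetic corpus.

## The conversation-stage model

The stage model is a message-level hidden Markov model over ordered stages
(default 5). The state space is stages × roles with the role observed, so
only the stage is latent; transitions go from a stage to itself or to the
next one (no skips), conversations start in stage 1, and they need not
reach the last stage. A transition happens after every message, with an
advance probability per (stage, role of the message just produced). A
message's emission probability is the product of its tokens' probabilities
under the (stage, role) unigram distribution; the vocabulary keeps words
occurring strictly more than 20 times and folds the rest into an UNK token.
All computation is in log space; `logsumexp` guards underflow.

Training is EM with exact forward–backward E steps. Emissions are
re-estimated from expected token counts and mixed with a uniform
distribution of weight `smoothing = 1e-6` to keep likelihoods finite (with
`smoothing = 0` the one-stage M step reproduces the per-role corpus unigram
exactly — a useful closed-form check). The initialization follows the
standard recipe for this model — every stage starts at the per-role corpus
unigram, with uniform advance probabilities across stages — plus two
necessary refinements:

* a small multiplicative perturbation (scale 1e-2, seeded) on the
  emissions, because the exact symmetric initialization is an EM fixed
  point;
* `advance_init = 0.15` rather than 0.5. An advance probability of 0.5
  implies two-message stages a priori; since the emissions start symmetric,
  the first E step is driven entirely by this duration prior, and EM locks
  into a basin where early stages collapse into slivers (we verified
  message-level stage accuracy ~0.5 from that basin, with either emission
  initialization). A value matching roughly uniform expected stage
  durations at typical conversation lengths recovers the planted stages at
  ~1.0 accuracy across seeds. The advance probability remains uniform
  *across stages*, which is the substantive content of "uniform
  transitions" for a left-to-right chain.

Decoding is Viterbi under the same constraints, with ties broken toward
staying in the current stage. A brute-force enumerator over all monotone
stage sequences serves as an independent oracle for both the likelihood and
the decoded path on short conversations. Stage-duration comparisons between
counselor groups use conversations of 40–60 messages, give positive and
negative conversations equal weight, and bootstrap over counselors.
Stage-characteristic words are ranked by the ratio of stage emission
probability to the stage-average probability, above a frequency floor.

## Linguistic coordination

For exchanges — an utterance by a speaker of group A immediately followed by
a reply from group B — the coordination of replier *b* to group A along
marker *m* is

    C^m(b, A) = P(reply exhibits m | initial exhibits m) − P(reply exhibits m)

with probabilities estimated over b's exchanges; a reply pairs only with the
immediately preceding other-role message. Markers with no exhibiting
initial utterance are undefined and excluded from the speaker's
macro-average; speakers need at least 10 exchanges. The group value is the
unweighted mean over speakers (a pooled-exchange variant is available via
`pool = TRUE`). Under the generator's exhibit chain the expected value is
`(base + delta) − base/(1 − delta)` (the stationary exhibit rate is
`base/(1 − delta)`), which is the analytic oracle used in validation:
planted `base = 0.2, delta = 0.1` gives 0.0778. `category_coordination()`
runs the same statistic with psycholinguistic category lexicons as markers
and tests per-category speaker values against zero with a signed-rank test.
On the default corpus counselors never emit emotion-category words, so
those categories are reported as undefined rather than zero — the
category-coordination validation plants category markers as the injection
channel instead.

## Perspective change

Three texter-language trajectories per conversation fifth and outcome
group, each a ratio of lexicon-hit counts pooled over texter messages:
future (or past/present) words over all tense words; first-person-singular
pronouns over first-singular plus third-person pronouns; positive-emotion
words over positive plus negative. Denominators are category-internal
("relative amount ... versus"), not all-token counts. Lexicon entries may
carry a trailing `*` wildcard, in the style of stem-based category
dictionaries. Bootstrap CIs resample conversations.

## Outcome prediction

A balanced dataset keeps labeled conversations strictly longer than 30
messages and subsamples the larger class. Features are computed on the
first x% of messages only (x over message count): counselor hedge and
check-question rates, mean cosine similarity of counselor messages to the
preceding texter message, per-stage Viterbi durations on the prefix, mean
per-message lexicon sentiment (the scorer is pluggable), mean message
length, per-stage averages of each per-message feature (stage
conjunctions; stages the prefix never reaches contribute zeros), and
optionally counselor unigram/bigram counts above corpus frequency 5.

The classifier is logistic regression fit by batch gradient descent on the
mean negative log-likelihood, with L1 regularization when n-gram features
are present and L2 otherwise (intercept never penalized; regularization
strength default 1e-2). The step size is 1/L with L the Lipschitz constant
of the smooth part, and L1 uses proximal soft-thresholding, so descent is
monotone and the L1 solutions satisfy the subgradient optimality conditions
checked in the tests. Features are standardized per fold on the training
split only. Evaluation is stratified 10-fold cross-validation with AUC by
the rank statistic (equal to the trapezoidal ROC integral; cross-checked
against an independent implementation). The nested feature ladder compares
consecutive models with a paired bootstrap over held-out scores.

## What the synthetic validation shows — and what it does not

Passing tests establish that each implementation recovers the effect it
measures when that effect is planted, at the planted size, and reports
chance-level results when it is absent. The generator's conversations are
bags of synthetic identifiers with planted channels: they have no
word-order semantics, no topic mixture within stages, no missing or
system messages, no texter dropout, and outcome labels are
missing-completely-at-random only in the sense that every conversation is
labeled. Effect sizes on real counseling corpora, and the behavior of the
regular-expression classifiers on natural language, are not established by
these tests; the classifiers are validated only on their exemplar phrases
and the lexicons are open approximations of licensed dictionaries.

## Problem sizes used in the validation

Module tests run on 120-conversation corpora; stage recovery uses 200
conversations; coordination recovery uses ~9,000 exchanges per marker;
the divergence-monotonicity check runs 10 independent 400-conversation
corpora; prediction uses the 200-conversation corpus balanced to ~140. The
full test suite and the acceptance script each complete in a few minutes on
one CPU.
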