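---
title: "Modelling pseudoword valence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pseudoword valence: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudovalence)
```

## The scientific problem

Valence — how pleasant or unpleasant a stimulus feels — is a central
dimension of word meaning, and empirically it is predictable from both the
surface form of a word (which letters and letter pairs it contains) and from
its position in a distributional semantic space. Pseudowords, being novel
strings, have no stored meaning, yet raters judge their valence with real
consistency. This package implements the computational machinery for
studying that phenomenon: train valence models on rated words, transfer them
to never-seen strings, collect (or simulate) best–worst judgments on those
strings, convert the judgments to continuous indexes, and ask which
predictor family — letters, bigrams, embedding dimensions, or the valence of
orthographic/semantic neighbors — explains the observed indexes best.

## The valence model

The core estimator is ordinary least squares of mean valence ratings on
feature blocks selected by `feature_spec()`:

* **letters** — 26 occurrence counts;
* **bigrams** — 676 interior ordered-pair counts;
* **boundaries** — 26 + 26 indicators for the first and last letter,
  written `<b` and `s>`;
* **dimensions** — the string's composed embedding vector (below).

Seven canonical combinations are fit by `seven_model_specs()`. Whenever
bigrams enter a model the boundary indicators enter with them, because
word-boundary markers are conventionally treated as bigrams; letters +
bigrams therefore spans 754 columns, and the full model 754 + *D*.

Two numerical facts shape the implementation:

* **Rank deficiency is the normal case.** Most of the 676 ordered letter
  pairs never occur in a lexicon of realistic size, and letter counts are
  *exact* linear combinations of bigram + boundary counts
  (`count(x) = start_x + sum_y count(yx)`). We therefore solve the
  least-squares problem by SVD with a relative singular-value tolerance of
  `1e-10`, returning the minimum-norm solution and recording constant
  columns as aliased, rather than silently dropping columns the way `lm`
  does. A corollary worth knowing: letters + bigrams and bigrams-only span
  the same column space and fit identically — when those two rows of a
  comparison table coincide, nothing is wrong.
* **Fits require n > p.** With fewer observations than columns the
  minimum-norm solution interpolates and every fit statistic is
  meaningless, so the fit refuses and advises a larger lexicon or a smaller
  spec. Observed best–worst indexes for modest item sets are therefore
  always regressed on *predicted-valence columns* (univariate models), not
  refit on wide feature blocks.

Model quality is reported as in-sample R² (`1 - RSS/TSS`), r
(`cor(fitted, observed)`, the square root of R² in-sample, reported
separately to keep comparison tables conventional) and AIC under the
Gaussian convention `AIC = n·ln(RSS/n) + 2(k + 1)` with `k` the estimated
rank including the intercept and `+1` for the error variance. AIC additive
constants differ across software; orderings are the comparable quantity,
and both R²- and AIC-rankings are reported side by side. Evaluation is
in-sample throughout, matching standard practice for this design; no
cross-validation is attempted.

Predictions are deliberately not clamped to the 1–9 rating scale — extreme
strings can legitimately score outside it.

## Subword composition

A vector for an arbitrary string is the **sum** of the vectors of the
character 4-grams of the boundary-wrapped string (`"bus"` →
`<bus`, `bus>`), optionally plus a stored whole-string vector. Sum (not
mean) is the fastText-style convention; a `normalize = "mean"` mode exists
because the choice only rescales features when string length is constant
but changes cross-length predictions. 4-grams missing from a table are
skipped and counted; a string with *no* covered 4-gram is an error. Only
n = 4 is exercised against ground truth; other n are supported but
untested.

In-memory tables keep n-gram and whole-word vectors in separate namespaces,
because a 4-letter word and an identical interior 4-gram are different
objects. The flat `.vec` text format has a single namespace, so the reader
classifies keys by rule — boundary marker present, or exactly n characters,
means n-gram — and cannot represent the (synthetic-data-only) collision; we
accept that as a file-format limitation.

## Stimulus design

Candidates are screened (`filter_candidates`) for whole-word vectors (a
pretrained embedding model that has "seen" a pseudoword, e.g. through corpus
typos, gives it an unfair information channel), duplicates, a manual
exclusion list standing in for human readability/pseudocompound screening,
and — an addition needed for synthetic tables with partial 4-gram coverage —
non-composability.

`stratified_uniform_sample` slices the predicted-valence range into
`n_slices = 25` equal-width intervals and draws equal quotas per slice,
topping up one item at a time from the nearest non-exhausted slices. The
published design this mirrors used empirical, unequal tail slices; the
equal-width rule is the reproducible default and explicit breakpoints can
be imposed upstream via the exclusion list.

`build_trial_set` runs one seeded permutation of the items per appearance
round and chunks it into trials; when item count divides trial size the
construction is duplicate-free by construction, otherwise a repair pass
swaps members across trials (never breaking the exact appearance counts)
until no trial repeats an item. "Latin-square" assignment is
under-specified in the literature this follows; this construction satisfies
the stated constraints — every item exactly `appearances` times, no
within-trial repeats, seed-reproducible — and that is all we claim.
`assign_sessions` partitions trials into disjoint sessions, allowing a
short final session (7,500 trials at 45 per participant gives 166 full
sessions plus one of 30 — hence 167 participants) rather than padding with
repeated trials, and appends the same catch trials to every session.

## Value learning

Each best–worst choice on a k-item trial implies 2k − 3 ordered pairs: best
beats the other k − 1, and the k − 2 middle items beat worst; middles are
never compared with each other. Scores start at 0.5 and are updated
Elo-style over `n_passes = 100` passes; within each pass all implied pairs
are visited in a fresh seeded random order, and for a pair (w, l):

```
p  = 1 / (1 + 10^((v_l - v_w) / s))        # expected win, s = 0.4
v_w <- v_w + eta * (1 - p)
v_l <- v_l - eta * (1 - p)
```

with `eta` decaying linearly from 0.1 to 0.001 across passes, and the
reported score the mean over the trailing 10% of passes. These constants
are tuned on the package's own recovery fixtures (150 items, 30
appearances, 6 per trial, rater noise at half the latent SD recovers the
latent order at Spearman ρ ≈ 0.97) and are all exposed in `vl_config()`;
they are conventions, not estimates. Score location and scale are
arbitrary — all downstream use is correlational, and the tests assert that
affine rescaling changes no reported r or R².

Catch trials (known-answer real-word trials) are excluded from scoring
input; a participant with more than one catch error (wrong best and wrong
worst count separately) is dropped with all their records. Split-half
reliability randomly halves the *participants*, scores each half
independently, and correlates over shared items, dropping items present in
only one half.

## Neighbors

Orthographic distance is the optimal string alignment (restricted
Damerau–Levenshtein) distance with unit costs: insertions, deletions,
substitutions and adjacent transpositions, with transposed substrings never
re-edited — so `osa("ca","abc") = 3` where unrestricted
Damerau–Levenshtein gives 2. Because the distance is integer-valued,
minimal-distance ties are common; all tied neighbors are returned and their
valences averaged unweighted. Semantic neighbors minimize cosine distance
between the query's composed vector and stored word vectors (composed
vectors are used for queries only; recomposing the lexicon would be the
alternative, noted and not taken). Poorly-embedded "hub" words that win a
disproportionate share of queries distort this analysis; `hub_report`
flags words above a 5% share, and exclusion remains an explicit configured
list — detection assists, it never silently removes.

Scans are exhaustive (full query × lexicon matrices); at the scale this
method is used (thousands of words), approximate indexes are unnecessary.

## The synthetic world

`sim_config()` fixes the generating conditions once:

| parameter | default | meaning |
|---|---|---|
| `n_words` | 5,000 | lexicon size (study-scale runs use 2,000) |
| `word_length` | 3–8 | uniform word lengths |
| `letter_effect_sd` | 0.4 | SD of per-letter valence effects (rating pts) |
| `dimension_effect_sd` | 0 | SD of embedding-projection effect |
| `n_dims` | 300 | embedding dimensionality |
| `noise_sd` | 0.5 | residual rating noise |
| `valence_anchor` | 5 | scale midpoint |
| `rater_noise` | 0.5 × SD(latent) | Gumbel utility-noise scale |
| `compliance_rate` | 0.86 | mirrors the 167/194 retention of the design emulated |

Latent word valence is `anchor + letter effects + dimension term + noise`,
clipped to [1, 9]. With ~5.5 letters per word these defaults give letter
signal roughly twice the residual variance — a deliberately learnable
regime. Raters draw one Gumbel-noise utility per item and pick argmax/argmin
(a multinomial-logit choice model, chosen for analytic tractability; no
claim is made that humans are logit choosers). Non-compliant participants
answer uniformly at random on *all* trials including catch trials, so the
screening logic is genuinely exercised. Candidate pseudowords splice halves
of two lexicon words or substitute one letter — a naive stand-in for
phonotactic generators, sufficient to give candidates lexicon-like bigram
statistics but making no claim of human readability.

What passing tests on this world do and do not show: they validate the
*machinery* — that the pipeline recovers planted structure, ranks the
truly generative predictor first in both a letters-planted and a
neighbor-planted world, and is calibrated under the null. They do not show
that human pseudoword valence works this way; real lexicons have correlated
letter/bigram/semantic structure, real embeddings are not isotropic
Gaussians (in particular, synthetic spaces exhibit no natural hubness), and
real raters are not logit choosers with i.i.d. compliance.

## Problem sizes and runtime choices

The package's own validation runs use: 2,000-word lexicons with 300
embedding dimensions for the study-scale worlds; a 5,000-word lexicon for
letter-effect recovery (r ≈ 0.999); the 150-item / 30-appearance / 6-per-
trial fixture for score recovery (ρ ≈ 0.97); 1,000 replicates for F-test
null calibration; and the full 1,500 × 30 / 6 design for the arithmetic
checks. These sizes were chosen once as the smallest at which the planted
effects are estimated cleanly.

## Known limitations

* Phoneme-level features are out of scope (pseudoword pronunciation is
  indeterminate in a non-transparent orthography).
* Embeddings are consumed, never trained; n-gram hashing schemes of real
  subword models are abstracted away as a key → vector table.
* The value-learning scorer is one concrete instantiation of an Elo-style
  family; alternative scalers (counting scores, Bradley–Terry maximum
  likelihood) appear only as test oracles.
* In-sample evaluation mirrors the practice of the designs emulated; a
  held-out mode would need larger item sets than the best–worst budget
  typically allows.
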