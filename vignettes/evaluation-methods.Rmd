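---
title: "Methods: blinded paired evaluation of patient-education content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blinded paired evaluation of patient-education content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eduscore)
```

## The design

`eduscore` evaluates two arms of personalized patient-education documents in
a paired design: each patient profile yields one AI-drafted and one
clinician-written document, and every metric is compared within profile via
the difference `d = x_AI − x_clinician`. Documents are anonymized and
shuffled before rating (`blind_and_randomize()`); the blinding key is a
bijection kept apart from the blinded set, and metric computation is
invariant to blinding (the package tests this), so the order of operations
does not affect results.

Seven metric families are computed per document: words per minute, four
grade-level readability indices, a weighted guideline-concordance accuracy
score, and three 100-point rubric instruments.

## Tokenization and the readability indices

All four indices consume one set of token statistics. The choices here are
deliberately deterministic and auditable rather than linguistically
sophisticated:

- **Sentences.** `.`, `!`, `?` terminate a sentence, except a period that
  sits inside a decimal number, is followed by a lower-case letter, or
  closes a fixed abbreviation list ("Dr.", "e.g.", ...). Commercial
  readability tools do not publish their segmentation dialect, so exact
  numeric agreement with any particular tool is out of reach; what the
  package guarantees instead is a fixed, testable rule.
- **Words.** Maximal runs of alphanumerics with internal hyphens or
  apostrophes; purely numeric tokens count one syllable. The same word
  count feeds words per minute, for internal consistency.
- **Syllables.** Vowel groups (`a e i o u y`), a silent trailing "e"
  discounted unless preceded by a consonant + "l" ("table"), minimum one
  per word, with an editable exception table
  (`inst/extdata/syllable_exceptions.tsv`) consulted first. The table ships
  with a handful of clinical words the heuristic undercounts
  ("osteoarthritis" → 6). Reproducibility is preferred over dictionary
  coverage: unknown words fall back to the heuristic deterministically.
- **Fog complex words.** Polysyllables (≥3 syllables) excluding
  capitalized non-sentence-initial tokens (a proper-noun proxy) and
  hyphenated compounds. The classic exclusion list is ambiguous about
  inflectional endings; `-es`/`-ed` forms are *not* discounted here, a
  documented simplification that keeps the rule auditable.
- **SMOG.** The general scaling formula `1.0430·√(30·P/S) + 3.1291` is
  applied at any sentence count; a warning notes when `S < 30`, since the
  formula was calibrated on 30-sentence health-education samples.

## Guideline-concordance accuracy

Each treatment's five society stances are consolidated to the modal
category; `consensus_n` is the modal bloc size, mapped to weights 1 / 0.75 /
0.5 / 0.25. Two genuinely open points were fixed as follows:

- **Tie rule.** When categories tie for modal size the consolidated
  category is `INC` with the tied bloc size — disagreement among societies
  is the operational definition of inconclusiveness.
- **Agreement** means identical category, not merely the same direction,
  matching the category-level weighting structure.

A document's raw score sums `score × weight` over the *distinct* treatments
it mentions ("treatments mentioned" is a set notion; duplicates collapse).
The default `literal` mode ignores mention polarity, which is how the
instrument is defined; a `polarity_aware` mode that sign-flips discouraged
mentions is available behind a flag as an extension. The raw sum is
unbounded, so for 6-point-scale reporting `normalize_accuracy()` anchors the
table's maximum achievable positive sum at 6 and clips below at 0. That
normalization is one defensible reading of a scale whose construction is not
fully specified; the raw score is always reported alongside.

The authoritative society table is a runtime CSV input. The shipped
`guidelines_demo_synthetic.csv` is a *synthetic demonstration table* — 12
plausible knee-osteoarthritis treatments — and is not an extract of any
society's guidance.

## Rubric instruments and adjudication

Personalization is 30/40/30 (relevance, individual relevance, detail
level); comprehensiveness and safety are five 20-point dimensions each
(medication treatment, non-medication treatment, lifestyle advice,
psychological support, disease management). Raw rater points are integers
in `[0, max]`.

Adjudication operates **per dimension**: a flag requires a strictly
greater-than-10-point gap (a 10-point difference is tolerated), and a
flagged dimension resolves either to an agreed consensus value or to the
median of the two primary raters and a third rater. Two unstated details
were fixed as package decisions:

- Agreeing dimensions combine as the arithmetic mean of the two raters
  (unbiased, conventional; half-points allowed in adjudicated output).
- The three-rater median is taken per dimension, matching the granularity
  of the trigger.

Both choices are permutation-invariant in the raters, which the tests check
exhaustively on small score grids.

## Paired statistics

Normality of the paired differences is screened with Shapiro-Wilk at
α = .05 — a standard choice at n = 50 pair counts — selecting the paired
*t* test (mean/SD reporting) or the Wilcoxon signed-rank test (median/IQR
reporting). Numerical details:

- Wilcoxon drops zero differences (classic variant; the Pratt variant is a
  non-goal) and uses midranks for ties. For ≤12 effective pairs the
  two-sided p-value is exact: the null distribution of the doubled rank sum
  is built by convolution over all sign assignments, so ties are handled
  exactly. Above 12 a normal approximation with tie and continuity
  correction is used. The cutoff keeps the exact path at trivial cost while
  covering every case where the approximation is questionable.
- Tests are two-sided throughout; p-values print to three decimals with
  `<.001` below that. The significance flag is strictly `p < .05`.
- Differences with zero variance are rejected by the *t* test with an
  explanatory error; the AUTO policy falls through to Wilcoxon in that
  case.

No multiplicity correction is applied across the metric families; the
report is one row per metric and interpretation is left to the reader.

## The synthetic-data generator

The generator emulates the *shape* of a 50-profile, two-arm study, not
clinical prose. Design and defaults:

- **Text.** Documents are assembled from a curated knee-osteoarthritis word
  bank whose syllable/letter counts are computed by the package's own
  counter at build time, so every document carries an exact token ledger
  and `compute_token_stats()` round-trips it exactly (a tested invariant
  over 200 random targets). Per document, a target Flesch-Kincaid grade is
  drawn per arm (defaults AI 11.56 ± 1.08, clinician 12.67 ± 0.95 — the
  magnitudes the evaluation is designed to detect) and converted to a
  syllables-per-word target at 12–18 words per sentence and 30–45
  sentences.
- **Efficiency.** Words per minute are lognormal per arm with medians
  530.03 (AI) and 37.29 (clinician) and log-SDs 0.14 / 0.08 chosen to give
  interquartile ranges of realistic width; authoring minutes are derived
  as `W / WPM`.
- **Accuracy.** In the real instrument, accuracy is deterministic given a
  document's expert-annotated mentions — there is no rater noise on this
  metric. The generator therefore realizes a per-profile latent target
  (clinician base N(3.5, 0.8) on the raw scale, AI shifted by +0.55 by
  default) through randomized greedy mention planting against the guideline
  table; the document-level variability is the quantization noise of that
  subset selection (SD ≈ 0.3 on the raw scale).
- **Raters.** Rater points are truth + rounded Gaussian noise (default SD
  3 points per dimension), clipped to the dimension range. With probability
  `p_disagreement` (default 0.05 — a placeholder; no empirical disagreement
  frequency is available) one dimension of the second rater is pushed
  strictly past the threshold, guaranteeing an adjudication path; a third
  rater near the truth is always generated.
- **Reproducibility.** All randomness flows from one master seed through
  named substreams (text, table, raters, timing, mentions, blinding), so
  components are independently reproducible and a cohort is byte-identical
  under the same seed.

What passing tests on such cohorts shows: the pipeline's arithmetic,
adjudication logic, calibration and power behave correctly under the
configured conditions. What it does not show: anything about real clinical
text — lexical realism, annotation difficulty, rater psychology, or the
true effect sizes of any particular authoring method.

## Calibration and power

Two simulation checks accompany the pipeline, at problem sizes chosen to
make Monte-Carlo error small relative to the quantities checked:

- **Type-I error.** 2,000 replicate null cohorts (both arms identical in
  distribution, n = 50 pairs, full rater-and-adjudication path): each
  paired test's rejection rate at α = .05 must lie inside the exact
  binomial 99% envelope around 0.05.
- **Power / recovery.** 500 replicate cohorts at a +0.5 accuracy shift:
  the paired comparison rejects in well over 80% of cohorts, and the mean
  recovered arm difference matches the configured shift; rubric shifts are
  recovered within Monte-Carlo tolerance the same way.

## Known limitations

- The syllable heuristic (and hence FK, Fog, SMOG) is an approximation;
  exception-table coverage is minimal by design. English only.
- The accuracy normalization to a bounded scale is one defensible
  construction, not a validated instrument.
- Rubric band anchors are documentation, not enforced scoring logic; the
  package does not model rater deliberation or compute reliability
  coefficients (kappa/ICC).
- The generator's defaults describe a plausible study shape, not any
  specific clinical corpus; effect sizes and noise levels are configuration,
  not estimates.
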