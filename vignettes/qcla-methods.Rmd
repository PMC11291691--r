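---
title: "Question-based computational language assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Question-based computational language assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcla)
```

## The measurement problem

Question-based computational language assessment (QCLA) elicits a small set
of descriptive words in answer to a targeted question — here, "describe the
emotional state of this narrative with five words" — and quantifies those
words with a distributional semantic model instead of, or alongside,
conventional rating scales. The package implements a complete two-phase
design: Phase-1 participants write a narrative about one of four assigned
emotional states (harmony, satisfaction, depression, anxiety), describe it
with five words and fill in PHQ-9, GAD-7, SWLS, HILS and the 24-item PAQ
(alexithymia); Phase-2 participants read one narrative each and produce the
same word and scale responses about its author. The analytic questions are
(a) whether the word responses classify the four states better than the
rating scales, and (b) whether narratives written by high-alexithymia
authors are harder to classify.

## The semantic model

Word meaning is represented by latent semantic analysis over a corpus of
short word responses. Each response is one *context*. From the corpus we
build a word-by-word co-occurrence table in which cell $(i, j)$, $i \neq j$,
counts the contexts containing both words and the diagonal counts the
contexts containing the word; within one context duplicate tokens count
once. Cells are transformed by $\log(1 + x)$ and the table is factored by a
singular value decomposition. Word $i$'s vector is row $i$ of $U S$
truncated to the first $k$ dimensions (default $k = 300$) and renormalised
to unit length.

Numerical choices worth stating explicitly:

* **$\log(1+x)$, not $\log(x)+1$.** A response-context co-occurrence table
  is dominated by zero cells, where $\log(x) + 1$ is undefined; $\log(1+x)$
  maps zeros to zeros and preserves sparsity and symmetry.
* **$US$ rows, not raw $U$.** Scaling by the singular values keeps the
  dimensions ordered by accounted variance in the word vectors themselves.
  Because the classifier consumes *the first $d$ dimensions*, this ordering
  is load-bearing. Raw-$U$ vectors are available via
  `build_space(..., weighting = "u")`.
* **Sign canonicalisation.** An SVD is determined only up to a sign per
  singular vector. We force the largest-magnitude entry of each left
  singular vector to be positive, which makes the build bit-reproducible
  for a fixed corpus and lets tests assert exact equality across reruns.
* **No pruning.** Words occurring in a single context are retained; no
  stop-word list, stemming or frequency floor is applied.
* A requested $k$ above the numerical rank is clamped to the rank with a
  logged note.

A five-word response is embedded by summing the vectors of its
in-vocabulary words and renormalising to unit length. Out-of-vocabulary
words are skipped and counted; a response whose words are all unknown
cannot be represented and is excluded with a logged count rather than
imputed. Embedding the known subset (rather than dropping partially-known
responses) was an open choice; subset embedding keeps more data and the
`n_known` field makes the information loss visible.

## Classification

Emotions are classified by multinomial logistic regression under
narrative-grouped 10-fold cross-validation. Grouping is the critical
design constraint: all responses tied to one narrative (its author's
Phase-1 row and every Phase-2 evaluation of it) occupy the same fold, so a
model is never evaluated on a narrative it saw in training. Folds are
formed by shuffling narrative ids with a fixed seed and dealing them
round-robin, which balances fold sizes to within one narrative.

Within each training fold, a grouped 5-fold inner loop selects the number
of leading semantic dimensions $d$ from a geometric grid
$\{2, 3, 5, 8, 12, 18, 27, 40, 60, 90, 135, 200, 300\}$ (clipped to $k$) by
pooled held-out accuracy, with ties resolved to the smallest $d$. Accuracy,
not log-loss, is the inner criterion because the headline quantity of the
design is the correct-classification rate. Training pools Phase-1 and
Phase-2 rows; accuracy is computed on Phase-2 rows only.

Four feature families are supported: `words` (the first $d$ semantic
dimensions), `rs_totals` (the four scale totals; PAQ is a moderator, never
a feature), `rs_items` (the 26 PHQ-9/GAD-7/SWLS/HILS items) and
`words_plus_rs` ($d$ semantic dimensions concatenated with the four
totals, $d$ selected jointly in the inner loop). Scale columns are z-scored
with training-fold statistics; semantic dimensions are left raw since the
SVD already fixes their scale and order.

The fit itself is a standard penalised multinomial maximum likelihood
(`nnet::multinom` with weight decay). The default ridge $\lambda = 10^{-4}$
exists for numerical honesty: unpenalised multinomial likelihood diverges
on linearly separable data, which near-noiseless synthetic corpora produce
routinely. Predictions are computed by an explicit softmax over the stored
coefficients; exact probability ties break deterministically toward the
earlier class in the fixed order (harmony, satisfaction, depression,
anxiety).

## Evaluation layer

All result statistics flow from the 4×4 predicted-by-true confusion
matrix: per-class accuracy, precision, specificity, sensitivity and F1;
overall accuracy as trace over total. A metric whose denominator is zero
(for instance precision of a never-predicted class) is carried as an
explicit undefined marker (`NA`, rendered "–"), never as zero — this is
exactly the case that arises when a weak model never predicts one class.

Classifier pairs are compared by a Pearson chi-squared test on the 2×2
correct/incorrect table (df = 1, no continuity correction) with the phi
effect size $\varphi = \sqrt{\chi^2 / N}$. Published reports sometimes
compute $\varphi$ with an $N$ convention that differs from the table total
(e.g. pairs excluded listwise), so `compare_proportions()` exposes `n_phi`
and `phi_from_chisq()` reproduces a printed $\varphi$ from a printed
$\chi^2$ and $N$. Subgroup mean comparisons use the pooled-variance
independent-samples t-test (df $= n_1 + n_2 - 2$, matching the df
convention of the reports this design follows), variance comparisons the
two-tailed F-test, associations the Pearson correlation with the
t-transform p-value, and multiplicity control is Bonferroni
($p \le \alpha/m$).

## Rating scales and alexithymia stratification

Scale totals are plain sums of the item answers; the instruments'
published scoring for these short forms uses no reverse-keyed items in the
orientation the items are supplied here, and no reverse scoring is
applied. Records with missing or out-of-range items are excluded with a
logged count, mirroring the exclusion of incomplete surveys in this kind
of online design, rather than imputed.

Alexithymia groups are formed by a median split on the PAQ total, with the
threshold value included in the *low* group (low ⇔ PAQ ≤ threshold). The
default threshold is 68, the conventional split point for this design;
`median_threshold()` recomputes an integer threshold from a sample,
flooring the even-$n$ midpoint so the threshold has the same integer form.
Whether ties at the median belong to the low group is not derivable from
first principles; the ≤ rule is fixed and documented rather than guessed
per dataset.

## Language-based score estimation

Rating-scale totals are predicted from response embeddings by ordinary
least squares on the first $d$ dimensions, with $d$ selected by the same
grouped inner cross-validation, the criterion being out-of-fold Pearson
$r$. Every row receives an out-of-fold predicted score; the package
reports the correlation of those predictions with the empirical totals,
phase-1-to-phase-2 test–retest correlations for both the empirical totals
and the word-based estimates, and subgroup mean/SD panels with t/F tests.
Predicted scores are raw linear outputs, deliberately not clipped to the
scale range: clipping would shrink variance asymmetrically and bias the
subgroup comparisons the estimates feed.

## Word clouds

"Word clouds" here are ranked tables, not graphics. Every vocabulary word,
embedded as its own unit vector, is scored by a trained model — the class
logit for classification targets, the predicted total for scale targets —
and the top 25 words per target are reported with corpus frequencies
(ties: higher frequency, then lexicographic order). Significance screening
uses a label-permutation null: the model is refitted on permuted labels at
the same $d$, per-word scores are recomputed, and each word's p-value is
the usual add-one permutation fraction, Bonferroni-corrected across the
vocabulary. A permutation count too small to reach $\alpha/m$ triggers a
warning stating the achievable floor. The permutation construction was
chosen because it makes no distributional assumption about scores of
correlated unit vectors; 1000 permutations is the default. The
alexithymia-by-depression panel splits records at PAQ 68 and the PHQ-9
sample median (the PHQ-9 split point is not fixed by convention, so the
sample median is used) and scores words by ridge-stabilised cell-vs-rest
logistic models.

## The synthetic study generator

The generator exists so that every stage is testable without access to the
original deposit. It emulates, with one knob per mechanism:

* four balanced emotion conditions over 116 narrators and 232 evaluators;
* emotion vocabularies (150 words each) with controlled sharing — 20%
  between harmony and satisfaction, 10% between depression and anxiety, 2%
  otherwise — reflecting that harmony and satisfaction narratives draw on
  overlapping positive vocabulary;
* Zipf-distributed word frequencies (exponent 1.0) within vocabularies,
  giving realistic frequency skew for the cloud tables;
* word-choice noise of 0.15 (low-PAQ) versus 0.35 (high-PAQ narrators),
  encoding the direction that high-alexithymia narratives are harder to
  evaluate; Phase-2 words inherit the narrator's noise level;
* condition-congruent scale elevation of 5 total points with 80% bleed
  onto the same-valence sibling scale and item SD 1.5 — the bleed makes
  the rating scales discriminate the two valence clusters far better than
  the states within a cluster, which is what makes scale-based
  classification weak in this design;
* narrator PAQ from a normal(68, 20) truncated to [24, 168], so the
  conventional threshold 68 is a typical sample median;
* a training corpus of 3000 responses of 3, 5 or 10 words (emulating the
  varied elicitation lengths of word-norm corpora).

These defaults were fixed once as a realistic rendering of the study
conditions and are not tuned per analysis. What the generator does *not*
emulate: free-text narratives (Phase-2 "reading" is modeled as
condition-plus-noise regeneration), item-level psychometrics beyond a
shifted-mean integer model, response styles, and the lexical richness of
real English (synthetic tokens are ids, not words). Passing tests
therefore demonstrate that the pipeline recovers structure that is present
by construction — direction and ordering claims (words beat weak scales;
low-PAQ narratives classify better; noise degrades accuracy) — not that
real-data effect sizes are reproduced.

## Problem sizes and runtime choices

The package's own test suite runs the generator at reduced scale (40
narrators, 80 evaluators, 40-word vocabularies, $k = 60$, 4–5 outer and 3
inner folds), which keeps each property check in seconds while leaving
every mechanism engaged. The bundled acceptance script runs the full
default conditions ($k = 300$, 10 outer folds, 5 inner folds, the full
dimension grid). Directional invariants are checked across five generator
seeds.

## Known limitations

* The corpus and response vocabularies come from the same generator, so
  out-of-vocabulary handling is exercised by construction in tests rather
  than arising organically.
* `nnet::multinom` convergence at very small ridge on separable data can
  be slow; a fit that exhausts its iteration budget raises a convergence
  error rather than returning silently, and the inner selection loop
  treats such a candidate dimension as unusable.
* The permutation screen refits the full model per permutation; for large
  vocabularies and class targets this is the dominant cost and the
  permutation count should be budgeted against the Bonferroni floor
  warning.
* Undefined metrics propagate as markers; downstream aggregation must
  handle `NA` (the report writer renders them as dashes).
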