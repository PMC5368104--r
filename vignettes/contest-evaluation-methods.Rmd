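---
title: "Evaluating small-molecule identification contests: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating small-molecule identification contests: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molcontest)
```

molcontest evaluates methods that rank candidate structures for tandem-MS
challenges. This vignette explains the model behind each stage, the tunable
parameters and their defaults, what the synthetic data generator does and
does not emulate, and the design decisions taken where the conventions of
such contests leave room.

## The ranking model

A submission for one challenge is a set of (structure, score) pairs with
non-negative scores, higher better. Evaluation proceeds in three steps.

**Stereoisomer collapse.** Liquid-chromatography MS/MS cannot separate
stereoisomers, and participating tools disagree on how they enumerate them,
so candidates are grouped on the first InChIKey block — the 14-character hash
of the connectivity layer, identical across stereoisomers — and each group is
represented by its highest-scoring member (`collapse_stereo()`). Keeping the
maximum is the only choice consistent with scoring a method by the best
stereo-variant it proposed; it also makes the collapse idempotent.

**Tie-averaged rank.** Within a collapsed submission the correct candidate's
rank is its expected position over all orderings consistent with the scores:
with `B` candidates strictly above and `t` candidates sharing its score
(including itself), `average_rank = B + (t + 1) / 2`. The test suite checks
this closed form against exhaustive enumeration of tie permutations, and
checks the conservation law that the average ranks of *all* candidates sum to
`TC (TC + 1) / 2`. Average ranks are preferred to worst-case ranks because
worst-case ranking rewards adding random jitter to break ties; the average is
invariant under any strictly increasing transform of the scores (also
tested). For counting statistics (Top X, Formula 1, Medal score) non-integer
ranks are rounded **up** — a rank of 1.5 is counted as 2 — so a method never
gains a Top-1 from a coin-flip tie.

Tie detection defaults to exact equality of parsed score values. Some tools
emit floats that differ only in the last digits for chemically equivalent
candidates; `rank_correct(tie_epsilon = )` optionally groups scores within an
absolute tolerance. The default is 0 (off) because any positive epsilon makes
"tied" intransitive and breaks the conservation law above; turning it on is
an explicit analysis decision.

**Missing ranks.** An entry may skip a challenge, or omit the correct
candidate (e.g. after top-k truncation). Both yield an explicit missing rank.
Missing is substituted only at well-defined points: medal assignment treats
missing as worst (and never awards a medal to a missing entry — winners are
declared among submitted results); the rank-matrix display substitutes the
challenge's official candidate count; location statistics (mean, median,
quantiles) exclude missing by default, with
`summarize_entries(missing_rank = "candidate_count")` as the labelled
sensitivity mode, because silently mixing the two conventions makes means
incomparable across entries with different coverage.

Submitted candidates that are absent from the official candidate list are
kept by default (there is no published rule pruning them); a strict mode
(`rank_correct(strict = TRUE, universe = )`) rejects them instead. Both
behaviours are exercised in tests.

## Contest statistics

`summarize_entries()` computes the comparison panel per entry: Top 1/3/10
(on rounded ranks), Top-1 split by ion mode, mean/median rank, mean/median
RRP with `RRP = (TC − rank) / (TC − 1)` (1 best, 0 worst, defined as 1 when
`TC = 1`), rank quantiles Q10–Q90, Formula 1 score (points 25, 18, 15, 12,
10, 8, 6, 4, 2, 1 for rounded ranks 1–10) and Medal score (5/3/1 for ranks
1/2/3). The quantile estimator is linear interpolation between order
statistics (`stats::quantile` type 7): the estimator used for published
contest quantiles is not stated, so published quantile rows should not be
expected to match bit-for-bit.

Per-challenge medals (`assign_medals()`) give gold to the entry or entries
with the lowest average rank — a challenge has a winner even when nobody was
Top 1 — with joint positions on ties. After joint medals the next distinct
rank receives the medal of its *competition* position (after two joint golds,
bronze; no silver). Contest rules only state that joint positions are
possible; competition ranking is adopted as the standard sports convention,
with `ties = "dense"` available as the alternative. `olympic_tally()` orders
entries by gold, then silver, then bronze, and can first reduce to the best
entry per participant, which is how overall winners are declared.

## Consensus scoring and metadata

`combine_submissions()` builds the per-challenge union of candidates over the
component submissions, normalises each component by its per-challenge maximum
score, and returns the weighted sum; a candidate missing from a component
contributes `missing_value` (default 0 — penalised, not excluded). The
normalisation deserves a flag: published consensus entries do not print their
normalisation scheme, so per-challenge max-division was chosen here as the
simplest order-preserving way to make heterogeneous scores commensurable.
Results of weighted fusions are therefore methodologically comparable to, but
not numerically reproductions of, any published combined entry.

The metadata scorers mirror the standard non-spectral evidence sources:

* `refs_score()` — literature reference count, used as-is. Contest compounds
  tend to be well-studied chemicals, which is why this trivial scorer is a
  strong baseline.
* `lowest_id_score()` — lowest database identifier is best, mapped through
  `1/id` to satisfy the non-negative higher-is-better contract; any strictly
  decreasing transform induces the same ranking (tested).
* `db_presence_score()` — +10 points per queried database containing the
  candidate, designed to be *added* to a fragmenter score.
* `rt_score()` — a least-squares line `rt = a · descriptor + b` fitted on
  training compounds (`fit_rt_model()`, at least 3 pairs, non-degenerate
  descriptor variance), then
  `score = max(0, 1 − |rt_obs − rt_pred| / w)` with window `w` (default
  2 min, roughly the spread of gradient LC retention reproducibility). The
  exact functional form used by published retention-time entries is not in
  the main literature; this clamp is a non-canonical but transparent default.

`fit_weights()` grid-searches the weight simplex (step `grid_step`)
maximising Top-1 count on training challenges, tie-broken by Formula 1 score
— the same criterion one would use to tune a combined entry on a training
split. It returns the full grid so overfitting can be inspected; with few
training challenges the Top-1 surface is flat and the optimum is not unique.

## Spectra

`cosine_similarity()` matches peak pairs within a ppm tolerance (relative to
the pair's midpoint m/z) greedily in order of decreasing intensity product,
each peak used at most once, and returns the normalised dot product over
matched pairs. Intensities are square-root scaled by default — the common
variance-stabilising choice that prevents base peaks from dominating — with
`scaling = "raw"` available since published similarity baselines do not state
their scaling. Greedy matching equals the optimal one-to-one assignment
whenever each peak has at most one in-tolerance partner, which holds at
high-resolution tolerances (10 ppm default) for realistic peak spacings; the
tests compare against an exhaustive assignment oracle on small spectra.

`library_search()` filters a spectral library to precursors within a ppm
window (10 ppm default) and ranks survivors by cosine. A lone survivor is
returned regardless of similarity: precursor uniqueness alone can identify a
compound.

`split_train_challenge()` implements the similarity-based training/challenge
partition: a spectrum is training if and only if its best library similarity
is **strictly above** the threshold (default 0.85 — a similarity of exactly
0.85 stays a challenge) and it is not a named exception (exceptions force
spectra into the challenge set, e.g. to retain enough natural products).
The similarity function is pluggable and defaults to the module's cosine;
the official partitions of past contests used a different (MetFusion-style)
similarity, so this default will not reproduce official memberships — the
rule, thresholds and exception semantics are what is reproduced here.

`dedupe_spectra()` removes exact-duplicate peak lists and collapses repeated
measurements of one substance in one ion mode to the highest-maximum-intensity
spectrum; `filter_spectra()` applies the usual quality predicates (at least
2 peaks, maximum intensity at least 1e5 counts), both as configurable
defaults matching standard curation thresholds.

## The synthetic contest generator

`generate_contest()` exists so the whole pipeline is testable without contest
downloads. Its defaults are fixed study conditions, not tuning knobs:

* 208 challenges, 127 positive / 81 negative mode, matching the scale of a
  real contest season;
* per-challenge candidate counts log-normal with `meanlog = log(1114) − 0.5`,
  `sdlog = 1` (mean ≈ 1114 candidates, the average list size reported for
  real ±5 ppm candidate retrieval);
* stereoisomer duplicate rows at Poisson rate 0.1 per skeleton, with
  syntactically valid, contest-unique fake InChIKeys;
* decoy reference counts Pareto(shape 1) — heavy-tailed, like real literature
  counts — with a 1000× multiplicative boost on true compounds (true contest
  compounds are famous molecules; the boost size makes the refs-only scorer
  place truth in the top 2 for the large majority of challenges, the
  qualitative behaviour observed on real metadata);
* true-compound identifiers exponential with mean 5e4 against decoys uniform
  to 1e7 (old identifiers are common compounds);
* retention times `rt = 1.2 · descriptor + 3 + N(0, 0.3)` minutes over
  descriptors centred at 2.5 ± 1.5 — a plausible reversed-phase gradient
  calibration with logP-like descriptors.

Method behaviour (`method_profile()`) is a one-parameter quality model: the
true candidate's score is a `Beta(alpha, 1)` draw against uniform decoys, so
`alpha = 1` is an uninformative method (true rank uniform — verified
distributionally in tests) and `alpha → ∞` a perfect one; `tie_prob`
quantises scores to inject ties, `coverage` drops challenges, `top_k`
truncates candidate lists (which can delete the correct answer, emulating
methods that submit only their top 500). One global seed fans out to fixed
per-stage streams, so contests, submissions and spectra are individually
reproducible and byte-identical across runs.

What the generator does **not** emulate: fragmentation chemistry (library
spectra are random peak sets, not fragment patterns), correlation between
method errors (real fragmenters fail on the same hard compounds — consensus
gains here are therefore optimistic), mode-dependent method quality, and any
real chemical meaning in the fake InChIKeys. Passing tests on synthetic
contests validate the *evaluation machinery* and the *statistical direction*
of effects (quality ordering recovered by the tally, consensus beating
components, refs-score dominance), not the performance of any real method.

## Problem sizes and numerical choices

The test suite runs at deliberately modest sizes chosen as its own study
conditions: oracle-equivalence checks enumerate tie permutations up to 8
candidates; conservation checks use 1000 random submissions of up to 10
candidates; the quality-ordering and consensus study uses 100 replicates of
200-challenge contests with ~100-candidate lists and method qualities
alpha = 4, 2, 1 (plus three alpha = 2 components for the consensus arm);
retention-line recovery uses 300 training pairs against 2-standard-error
bounds. Score comparisons are exact double equality unless `tie_epsilon` is
set; similarity values are compared to the assignment oracle at 1e-9; the
cosine clamps at 1 to absorb floating-point overshoot on self-similarity.

## Known limitations

* No chemistry engine: structures are handled as precomputed InChIKeys, with
  `key_fun` as the adapter hook for SMILES/InChI conversion. Evaluation
  logic deliberately does not depend on a chemistry toolkit.
* The MetFusion-style library score used by some published metadata entries
  is not reimplemented; any external per-candidate score table can be fused
  via `combine_submissions()`, and the spectra module's plain cosine library
  score is the built-in stand-in.
* The CLI covers its documented outputs via flags only; there is no YAML
  config mirror.
* Candidate retrieval (mass-window database search) is upstream and out of
  scope; candidate lists are inputs.
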