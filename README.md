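# molcontest

Benchmarking toolkit for computational small-molecule identification from
tandem mass spectrometry (MS/MS), built around the evaluation machinery of
community identification contests.

In such contests, each *challenge* is an MS/MS spectrum of an unknown (but
database-retrievable) compound, together with a candidate list of isobaric
structures. Participants submit, per challenge, a plain-text table of
candidate structures with non-negative scores (higher = better). The
evaluation must then answer: *where did each method rank the correct
structure, and who won?* That is less trivial than it sounds, because

* MS/MS cannot distinguish stereoisomers, so candidates are collapsed on the
  first block of the InChIKey (the 14-character skeleton hash), keeping the
  **highest-scoring isomer**;
* methods emit tied scores, handled by the **tie-averaged rank**: with `B`
  candidates scoring strictly above the correct one and `t` candidates
  (including it) sharing its score, `rank = B + (t + 1)/2`, rounded **up** for
  counting statistics (a rank of 1.5 counts as 2 for Top-X);
* entries skip challenges, so missing ranks must be handled explicitly
  (worst-case at medal time, candidate-count substitution in displays, never
  silent imputation).

On top of per-challenge ranks the package computes the full comparison panel:
Top 1/3/10 counts, mean/median rank, relative ranking position
`RRP = (TC − rank)/(TC − 1)` in [0, 1], rank quantiles, the **Formula 1
score** (25, 18, 15, 12, 10, 8, 6, 4, 2, 1 points for rounded ranks 1–10),
the **Medal score** (5/3/1 for ranks 1/2/3), per-challenge gold/silver/bronze
(gold to the lowest rank among all entries, joint positions allowed), and the
**Olympic tally** (most golds wins, silver then bronze as tie-breaks).

It also ships the Category-3-style *consensus machinery* — per-challenge
max-normalisation and weighted summing of heterogeneous scores, plus metadata
scorers (literature reference counts, database presence at +10 a hit, lowest
database identifier, retention-time agreement from a fitted
hydrophobicity→RT line) — spectral utilities (MGF and plain-text peak lists,
ppm-tolerant cosine similarity with greedy peak matching, library search in a
precursor window, the strictly-above-0.85 training/challenge similarity
split), and a fully seeded synthetic contest generator so every stage is
testable without contest downloads.

## Worked example

```r
library(molcontest)

cfg <- contest_config(n_challenges = 50, candidate_meanlog = log(100),
                      candidate_sdlog = 0.5, seed = 2016)
contest <- generate_contest(cfg)
submissions <- generate_submissions(contest, list(
  method_profile("fragmenter_A", alpha = 8),
  method_profile("fragmenter_B", alpha = 3, tie_prob = 0.2),
  method_profile("fragmenter_C", alpha = 1.5, coverage = 0.9)
))
ev <- evaluate_contest(submissions, contest$solutions)
ev
#> <contest_evaluation: 3 entries on 50 challenge(s)>
#> # A tibble: 3 × 9
#>   entry         top1  top3 top10  gold silver bronze formula1 medal_score
#>   <chr>        <int> <int> <int> <int>  <int>  <int>    <int>       <int>
#> 1 fragmenter_A     3     9    24    35     12      3      267          23
#> 2 fragmenter_B     2     4    11     8     22     20      151          16
#> 3 fragmenter_C     0     1    11     7     17     21      105           1
```

`fragmenter_A` (the highest-quality simulated method, `alpha = 8`) ranks the
correct structure Top 1 in 3 of 50 challenges and Top 10 in 24, collects 35
per-challenge golds, and wins the Olympic tally (`ev$tally`, position 1).
Per-challenge detail lives in `ev$ranks`:

```r
head(ev$ranks, 3)
#>   entry        challenge_id  average_rank rounded_rank n_candidates   rrp missing
#> 1 fragmenter_A challenge-001           24           24          229 0.899 FALSE
#> 2 fragmenter_A challenge-002            5            5           44 0.907 FALSE
#> 3 fragmenter_A challenge-003            1            1          124 1     FALSE
```

An equal-weight consensus of the three methods:

```r
col <- collapse_stereo(submissions)
consensus <- combine_submissions(split(col[-1], col$entry))
cons_ranks <- rank_correct(consensus, contest$solutions)
sum(cons_ranks$rounded_rank == 1, na.rm = TRUE)
#> [1] 5
```

5 Top-1 hits versus 3 for the best single component — the consensus
effect the score-fusion module exists to study. Heat-map style displays come
from `build_rank_matrix()` + `autoplot()` (missing ranks shown as the
challenge's candidate count, log10-scaled), and `write_rank_matrix()` exports
them loss-free as CSV.

A thin command-line front end covers the same pipeline on files
(`validate`, `evaluate`, `simulate`, `matrix`, `combine`, `split`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "molcontest.R", package = "molcontest"))') \
  simulate --out-dir contest/ --seed 3 --n-challenges 20
```

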