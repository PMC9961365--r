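---
title: "Measuring statistical learning and rapid consolidation in the ASRT task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring statistical learning and rapid consolidation in the ASRT task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrtlearn)
```

## The task and what it measures

In the alternating serial reaction time (ASRT) task a target appears in
one of four horizontal positions and the participant presses the matching
key. Unknown to them, every other trial follows a fixed four-element
pattern while the interleaved trials are uniformly random: the stream
realises an eight-element template `P r P r P r P r` built from one of
the `4! = 24` orderings of the positions. Each learning block holds 80
trials (ten template repeats), and a session has 25 learning blocks
separated by rests.

Because of this structure, every trial from the third of a block onward
closes a *triplet* with the two trials before it. A triplet is
**high-probability** when its third position is the pattern successor of
its first position, and **low-probability** otherwise. Pattern trials
always close high-probability triplets; random trials do so with
probability 1/4, so high-probability triplets make up
`0.5 + 0.5/4 = 62.5%` of trials and low-probability ones 37.5%. Two
behavioural quantities follow:

* **statistical learning** — the growing RT advantage for
  high-probability over low-probability triplet trials, an implicit
  measure of sensitivity to the transition statistics;
* **general skill learning** — the overall speedup across blocks,
  independent of triplet probability.

Separating the two is the point of the design: they can move
independently, and rest-period manipulations may affect them
differently.

## Scores

After classification, trials are excluded if the response was wrong, the
triplet is a trill (`x-y-x`) or repetition (`x-x-x`; both are
pre-existing response tendencies, and both are always low-probability
triplets since the pattern successor of a position is never itself), or
the RT exceeds 1000 ms (strictly). The first two trials of each block
cannot be classified and are likewise ineligible. Participants are
dropped when task accuracy is below 80%, when they started at least five
blocks more than 1500 ms late, when their block-initial trials averaged
above 1000 ms, or when they were older than 35 years (rules that target
inattentive online participation). Exclusion reasons are assessed
independently on the raw trial, so they overlap, flagging is idempotent,
and the report's overlap-aware total is below the sum of per-reason
counts.

Blocks are aggregated in **units of five consecutive blocks** (1–5, …,
21–25). Within a unit, the statistical learning score is the pooled
median RT of eligible low-probability trials minus the pooled median of
eligible high-probability trials; medians are pooled over the unit's
trials rather than averaged per block, which is both closer to the
verbal definition of a per-unit score and more robust at the trial
counts a unit provides. The standardized score divides by the same
unit's mean RT; we use the per-unit denominator (the definition leaves
the window open) because it keeps the normalisation local to the RTs
being compared, and the choice is exposed as an argument of the scoring
layer rather than hard-coded. General skill is the unit median RT over
eligible trials of either category.

## Online/offline decomposition

To resolve dynamics within and between blocks, each 80-trial block is
cut into five bins of 16 consecutive raw positions (exclusions thin a
bin; they never move its boundaries). Per bin we compute the same
median-difference learning score and the bin median RT. Then, per
participant:

* **online change** of block *b*: bin-5 score minus bin-1 score
  (25 values);
* **offline change** of rest *b*: bin-1 score of block *b + 1* minus
  bin-5 score of block *b* (24 values).

The two operators are linear and telescope: the sum of all online and
offline changes equals the last bin score minus the first, a property
the tests assert exactly. Signs read: positive online statistical
learning = gain during practice; negative offline = forgetting over the
rest; positive online general skill = slowing within the block (fatigue);
negative offline = recovery across the rest. A bin with no eligible
high- or low-probability trials yields a missing bin score; change
scores touching it are missing, and participant means are taken over the
available entries.

## Generation task (process dissociation)

Explicitness of the acquired knowledge is probed with a generation task
under inclusion ("recreate the sequence") and exclusion ("avoid it")
instructions: four runs of up to 24 presses per condition. Runs in which
more than half of the classifiable presses are trills or repetitions are
removed (exactly half is kept — the rule is strict); a participant whose
runs are all removed in a condition is dropped there. The score is the
percentage of classifiable presses (3rd press onward, runs never
concatenated) closing a high-probability triplet under the participant's
own sequence. Trill/repetition presses stay in the denominator: after
any two presses exactly one of the four keys continues a
high-probability triplet, so chance is exactly 25% only for the
all-presses denominator. Scores near 25% under both instructions mean
the knowledge is implicit.

## Inference layer

One-sample t tests (change scores vs 0, generation ratios vs 25) are
computed from the closed form, with explicit degenerate markers at zero
variance. Mixed-design (split-plot) ANOVAs — unit × group, phase ×
group, condition × group — are delegated to `stats::aov` with an
`Error(participant/within)` stratum structure; the design is required to
be balanced (the sequential sums of squares then coincide with every
other type, which the output records), partial eta squared is computed
from stratum sums of squares, and no sphericity correction is applied —
the result carries an explicit uncorrected-df note instead of silently
borrowing one. Degenerate within-cell variance raises an error rather
than reporting divergent F values. Bayes-factor model averaging is out
of scope; the results schema reserves a field so externally computed
values can be merged.

## The cohort simulator

Every stage above is exercised against simulated cohorts, so the
pipeline is testable end to end without any raw data. Per trial the
generative model is

```
RT = baseline − skill(block) + fatigue(block, bin) − δ(block, bin)·[high] + ε,
```

floored at 150 ms, with `ε ~ N(0, noise_sd)` and

* `skill(b) = skill_gain · (1 − e^(−0.12 (b−1)))` — saturating general
  speedup (default total 80 ms);
* `δ(b, bin) = 25 · (1 − e^(−0.15 b)) + ramp · (bin − 1)/4` — the
  high/low gap: saturating growth across blocks plus a linear
  within-block ramp (default 4 ms from first to last bin) whose gain is
  not carried into the next block, producing online gains and offline
  forgetting of statistical knowledge;
* `fatigue(b, bin) = carry(b) + 5 ms · (bin − 1)` — within-block
  slowing; across each rest the accumulated fatigue is reduced by
  `offline_recovery` (default 20 ms = full reset), producing the
  within-block slowdown and post-rest speedup seen in general skill.

Errors are injected at rate 0.09 and overlong RTs (uniform on
(1000, 1500] ms) at rate 0.0024, matching the exclusion shares the
analysis expects to handle (≈9% incorrect, ≈0.24% above 1000 ms).
Self-paced rests are lognormal with `log μ = log 10.58`, `σ = 0.954`,
the two-parameter solution to a median of 10.58 s and mean of 16.67 s
(the lognormal cannot also match the reported SD of ≈25 s; documented
approximation). Fixed groups rest exactly 15 or 30 s. Block-start
latencies are `N(500, 150)` ms with an optional late-starter mode that
trips the quality-control rule. The within-block ramp default of 4 ms
was fixed from the magnitude of group-level online change t statistics
(≈3.5 at n = 90) given the participant-level score SD that median-based
bin scores imply (≈12 ms) — chosen once, before validation runs, and
not tuned thereafter.

Choices worth naming: RT noise is additive Gaussian (no distributional
claim is needed for median-based scoring, and the 150 ms floor rules out
non-physiological values); incorrect trials draw from the same RT model;
between-participant heterogeneity beyond seed-driven sampling noise is
not modelled. Consequently the simulator reproduces the *structure* the
analysis assumes — alternation, triplet probabilities, block/bin grids,
exclusion rates, rest distributions, online/offline asymmetries — but
not the skewed RT distributions, autocorrelated lapses, or
individual-difference spectra of real cohorts. Passing tests therefore
certify the computational pipeline and its invariants, not empirical
claims about human learners.

## Determinism and numerics

A single integer seed determines everything: per-participant sub-streams
are derived from `(cohort seed, participant id)` by a fixed integer
hash below 2^31, so cohorts are reproducible participant by participant
and byte-identical on re-export. Medians of even-sized sets are the
midpoint of the central pair. Undefined scores (a unit or bin without
eligible trials of a category) propagate as missing values, never as
zeros. The trial-level RT cutoff is applied in milliseconds before any
rescaling, so the standardized score's scale invariance holds for a
fixed eligible set.

Problem sizes used in validation were chosen to keep checks sharp but
quick: 10^5-trial streams for the 62.5/37.5 convergence (binomial SE
≈ 0.15 points), 500 generation runs (11,000 presses) for the 25% chance
level, 30 participants at 60 ms noise for recovering the programmed
learning effect within its 95% CI, and a 90-participant group — the
study's scale — for the online-gain/offline-forgetting pattern.

## Known limitations

* The alternating template is taken to start with a pattern trial at
  each block's first position; the published materials do not pin the
  delivered phase, and triplet probabilities are phase-invariant, but
  analyses of real exports should confirm the convention.
* Only the four trial-data-computable participant rules are
  implemented; exclusions that depend on external tasks (n-back
  performance, restarts, prior participation) must be supplied as
  caller-side flags.
* The ANOVA layer reports uncorrected degrees of freedom; where
  sphericity is in doubt, users should fit the same long tables with a
  dedicated mixed-model package.
* Whether the original analysis used a per-unit, per-participant, or
  grand-mean denominator for standardized scores is not stated; the
  per-unit choice here is a documented interpretation, switchable via
  the scoring functions' `standardize_by` argument.
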