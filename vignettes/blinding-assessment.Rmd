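---
title: "Assessing blinding in two-arm sham-controlled trials with blindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing blinding in two-arm sham-controlled trials with blindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blindex)
library(dplyr)
```

## The problem

Trials of manual therapy of the back are hard to blind: the active
intervention has a distinctive feel, and both participants and the staff who
measure outcomes may guess the allocation. A methodological (feasibility)
trial addresses this directly by asking every respondent, immediately after
a one-time session, *"To what extent do you know which intervention you
received?"* on a five-level scale — strongly/somewhat active, don't know,
somewhat/strongly control — and quantifying the answers with blinding
indices. `blindex` implements that analysis end to end for a two-arm
(active vs control) design with one participant role and any of three
outcome-assessor roles.

## The Bang blinding index

Within an actual-arm group of size $n$, collapse the five-level answers by
direction: $r_c$ guesses pointing at the arm actually received, $r_i$
pointing at the other arm, and $r_{dk}$ "don't know". With
$p_c = r_c / n$ and $p_i = r_i / n$, the arm-specific index is

$$\mathrm{BI} = p_c - p_i = \frac{r_c - r_i}{n}, \qquad
\widehat{\mathrm{Var}} = \frac{p_c + p_i - (p_c - p_i)^2}{n},$$

with a Wald interval $\mathrm{BI} \pm z_{1-\alpha/2}\sqrt{\widehat{\mathrm{Var}}}$.
The index runs from $-1$ (everyone guesses the opposite arm) through $0$
(balanced guessing) to $1$ (everyone correct), and reads as the proportion
correctly perceiving assignment *beyond chance*. When nobody ventures a
guess ($r_c + r_i = 0$) the index is mathematically undefinable; `blindex`
returns `NaN` and flags the estimate `undefined` rather than reporting 0,
because "everyone declined to guess" and "guesses exactly balanced" are
different findings.

The two arm indices can be summed into a study-level quantity. Report
tables conventionally print the sum of the *rounded* arm indices, so
`summed_bang()` defaults to that convention (`rounded = TRUE`); the exact
sum is available and documented, and the two can differ in the second
decimal (0.63 vs 0.62 on the packaged dataset). The summed variance is the
sum of arm variances. Intervals are never clipped to the index range — an
upper bound of 1.17 is printed as such.

Adequacy, as `classify_blinding()` operationalises it: an arm index within
$[-0.2, 0.2]$ (boundaries inclusive) suggests adequate blinding; a summed
index within $[-0.3, 0.3]$; for the James index, inadequacy is suggested
when the interval's upper bound falls below 0.5. Undefined estimates
classify as `undetermined`.

## The weighted James index

The James index is a study-level measure over the pooled respondents of
both arms:

$$\mathrm{BI}_J = \tfrac{1}{2}\Big(1 + P_{dk} + \sum_{ij} w_{ij} p_{ij}\Big),$$

where $P_{dk}$ is the overall "don't know" proportion, $p_{ij}$ are the
joint proportions of the four non-"don't know" cells, and the default
signed weights are $-1$ (strongly correct), $-0.5$ (somewhat correct),
$+0.5$ (somewhat incorrect), $+1$ (strongly incorrect). Equivalently,
$\mathrm{BI}_J = (1 + \bar{s})/2$ for a per-respondent score $s$ that is
$+1$ for "don't know" and the cell weight otherwise — the form the
bootstrap exploits. Under these weights the index lies in $[0, 1]$: 1 for
complete ambivalence, 0 for unanimous strong correct perception, about 0.5
under random guessing. The antisymmetric weights give the index a clean
swap identity — reversing the direction of every guess maps
$\mathrm{BI}_J \mapsto 1 + P_{dk} - \mathrm{BI}_J$ — which the test suite
checks on random tables.

Two points here were genuinely open and are package decisions, not
published facts. First, the weight scheme: the signed $(\pm 1, \pm 0.5)$
scheme is the unique conventional choice that simultaneously reproduces
every study-level value printed in the source report (1.00 for an
all-"don't know" assessor, 0.53 for participants, 0.79/0.67 for the other
assessors, 0.82 pooled). Second, the interval: the report does not state
how its James CIs were computed, so `james_ci()` uses a percentile
bootstrap over respondents (default 10,000 resamples, seedable). Constant
data give a degenerate interval at the point estimate, which reproduces
the printed `1 (1 to 1)`; for non-constant data the bootstrap interval is
close to, but not a reproduction of, the printed ones, and the package
does not treat those as targets. A closed-form James variance is out of
scope.

## Reconstructing counts from published estimates

Raw response tables are rarely deposited, but for the Bang index the
printed triple (point, CI lower, CI upper) at two decimals pins down the
integer counts: `reconstruct_counts()` enumerates every
$(r_c, r_i, r_{dk})$ with $r_c + r_i + r_{dk} = n$, recomputes the index
and interval, rounds half away from zero, and keeps the matches. On the
source trial every one of the eight printed arm-level estimates
reconstructs *uniquely*, and the per-assessor reconstructions pool to the
printed pooled-assessor indices — a nontrivial internal consistency check
that the test suite enforces. `study_fixture()` packages the resulting
respondent-level dataset (24 participants × 4 roles).

Strength-of-belief splits are not identifiable from collapsed counts. The
splits in the fixture are synthetic constructions, chosen once so that the
weighted James index reproduces all printed study-level values; the Bang
index is invariant to them. They are labelled as constructed wherever they
appear. Where the report printed two versions of one bound (0.63 in the
table, 0.64 in the text, for one assessor's active arm), the recomputed
value 0.637 supports the text; the reconstruction uses the text value and
treats the table entry as a rounding slip.

## Precision-based design

With the sample size fixed by circumstance, design interest is in the
confidence-interval half-width
$z\sqrt{[p_c + p_i - (p_c - p_i)^2]/n}$, maximised at
$p_c = p_i = 0.5$ — the conservative default of `bi_halfwidth()` — and its
inverse `bi_required_n()`, the smallest $n$ meeting a target width. The
generic variance-based form is implemented rather than any single planning
figure, because published planning numbers depend on assumption sets that
reports rarely spell out; on the source trial's $n = 26$, the worst case
gives a half-width of 0.384, and an informative-guessing assumption set
($p_c + p_i = 1$, $p_c - p_i = 0.573$) reproduces the planned 0.315 as an
inverse-consistency example only.

## Secondary outcomes

Range-of-motion contrasts (degrees, flexion/extension) are mean
differences with unequal-variance intervals from group summaries:
`welch_mean_diff()` uses the Welch–Satterthwaite degrees of freedom and is
verified in the tests against `t.test()` on raw data with identical
moments. The method choice is itself an inference: the source report does
not name its CI method, a pooled-variance interval fails to reproduce its
printed flexion CI, and the Welch interval reproduces both printed CIs
exactly at printed precision — the verification is a test, not an
assumption. Descriptives follow report conventions: median/IQR (type-7
quantiles) for quantitative data, counts with whole-number percentages for
categorical data. No formal between-group hypothesis tests are provided,
by design.

## The synthetic trial generator

`simulate_trial()` emulates the study design end to end:

* **Randomisation** — 1:1 allocation in permuted blocks drawn uniformly at
  random from sizes {2, 4} (the block-ordering rule was unstated; uniform
  draws are this package's choice), stratified by a binary covariate
  (prior manual-therapy experience, default prevalence 7/24). Within a
  stratum the arm imbalance never exceeds half the largest block at any
  prefix of the allocation sequence.
* **Guess behaviour** — per role, a multinomial
  $(\theta_{correct}, \theta_{incorrect}, \theta_{dk})$ over guess
  direction, with directional guesses "strongly" held with probability
  `strong_fraction` (default 0.5). Defaults are the study's observed
  pooled per-role proportions (participants 11/24, 4/24, 9/24, etc.), so
  the default scenario mimics the trial; the Bang index estimates
  $\theta_{correct} - \theta_{incorrect}$, which the tests verify at
  $n = 10{,}000$. Assessor guesses are independent of participant guesses
  given the arm — no shared-cue correlation is modelled.
* **Outcomes** — pre-intervention flexion/extension ROM are normal with
  per-arm means from the published baseline medians (127/132 and 43/44
  degrees) and sds back-derived from the baseline IQRs (17/9 and 19/13.5);
  post = pre + additive effect + residual noise, with effects and residual
  sds from the published change-score summaries (3.5/3.7 and 2.0/1.5;
  residual sds 7.9/4.3 and 5.7/5.3).

All randomness flows through one seeded generator: identical config and
seed give byte-identical CSV output. What the generator does *not* emulate:
correlated cues between respondents, evolving perceptions over repeated
sessions, non-normal or floor/ceiling-limited ROM, and missing data (the
source trial had none in its primary outcome). Passing simulation tests
therefore demonstrate correctness of the estimators under this idealised
model, not robustness to those real-data features.

## Numerical conventions and problem sizes

Indices are computed unrounded and displayed at two decimals, rounding
half away from zero (`bi_round()`); ROM quantities display at one decimal.
Normal quantiles are exact (`qnorm`, 1.959964 at 95%) — every printed
interval reproduces at two decimals either way. The bootstrap uses
percentile bounds with type-7 quantiles. Validation is strict: unknown
response/arm/role tokens, duplicate participant-role pairs and
inconsistent arms are rejected with row numbers; an empty dataset refuses
analysis rather than returning empty estimates; absent roles yield rows
flagged unavailable rather than disappearing.

The simulation-based checks use problem sizes chosen to make Monte-Carlo
error small relative to the asserted tolerances while keeping the suite
fast: 10,000 respondents for parameter recovery (tolerance 0.03), 2,000
replicates at $n = 200$ per arm for Wald coverage (95% ± 2 points; the
exact trinomial coverage at those parameters is 94.8%), 5,000 replicates
for Welch coverage (± 1.5 points), 1,000 random tables for the
reconstruction round trip.

## Limitations

The package assesses perception of assignment only; credibility and
expectancy constructs are not captured. James CIs are bootstrap-based and
will not numerically match reports that used a closed-form variance.
Reconstruction recovers collapsed counts, not strength splits, and only
when the printed precision pins them down — `reconstruct_counts()` reports
non-uniqueness honestly when it arises. The packaged fixture carries no
raw ROM measurements, since group summaries do not determine them.
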