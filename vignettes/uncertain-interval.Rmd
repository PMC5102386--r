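---
title: "Trichotomizing diagnostic test scores: the Uncertain Interval method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trichotomizing diagnostic test scores: the Uncertain Interval method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trithresh)
```

## The problem

A continuous diagnostic score is usually dichotomized at a single cutpoint:
score at or above the cutpoint, call the condition present; below, call it
absent. Whatever criterion picks the cutpoint — the maximized Youden index
being the most popular — the cutpoint necessarily sits in the overlap of the
two class distributions, exactly where the score is least informative.
Subjects near it are close to coin flips, and every single-threshold method
silently converts those coin flips into confident-looking diagnoses.

`trithresh` instead trichotomizes the score line into *negative /
inconclusive / positive*. The inconclusive zone, the **Uncertain Interval
(UI)**, is anchored at the intersection of the two class densities — the
point where a score is equally likely under either class — and is grown
outward only as far as the scores inside it remain genuinely inter-mixed.
Scores outside it form the **More Certain Interval (MCI)**: below-UI scores
are called negative, above-UI positive. Because most misclassifications
cluster around the intersection, excising the UI raises the correct
classification rate (CCR) of the decisions that are still made.

## The model

Let $D_0$ and $D_1$ be the score distributions of subjects without and with
the condition (orientation fixed: higher score, more disease). Within a
candidate interval $[l, u]$ containing the intersection $x^\*$, classify the
interval's subjects by $x^\*$ itself and count
$TN$ (negatives $\le x^\*$), $FP$ (negatives $> x^\*$),
$TP$ (positives $> x^\*$), $FN$ (positives $\le x^\*$). The within-interval
sensitivity and specificity
$$Se_{UI} = \frac{TP}{TP+FN}, \qquad Sp_{UI} = \frac{TN}{TN+FP}$$
measure how *decidable* the interval still is: at perfect uncertainty both
equal $0.5$. The UI is the largest interval (most subjects; ties broken by
widest score range, then smallest lower bound) satisfying
$$Se_{UI} \le s, \quad Sp_{UI} \le s, \quad \min(TP, FP, TN, FN) \ge 1,$$
with the *selection bound* $s = 0.55$ by default, i.e. $TP/FN \le 1.22$ and
$TN/FP \le 1.22$ — a small tolerated positive bias over exact balance. For
strong tests the overlap can be too thin for any feasible interval; the
search then reports *not found*, which is a meaningful diagnostic, not a
failure.

### Parameters that matter

* `select` ($s$, default 0.55, must lie in (0.5, 1)) — the ceiling on
  within-interval Se and Sp. Larger values widen the UI and remove more
  subjects from decision-making; 0.55 tolerates odds of at most 1.22:1
  between correct and false calls inside the interval.
* `intersection` (`"kde"` default, `"normal"`) — the density-crossing
  estimator (below).
* `level` (TG-ROC, default 0.9; 0.95 also conventional) — the pre-selected
  Se/Sp level defining the comparator's Valid Range.

## Estimating the intersection

The default estimator fits a Gaussian-kernel density per class (Silverman's
rule-of-thumb bandwidth, a shared 512-point grid padded by three bandwidths)
and locates crossings of the two curves by linear interpolation. Crossings
strictly between the two class sample means are preferred, and among them
the one nearest the mean midpoint is returned. Sampling noise in weak tests
can push the relevant crossing slightly past a class mean (with
$D_1 = N(1, 1.5^2)$ the population crossing at $0.90$ sits next to the mean
at $1$), so crossings within one mean-gap of the between-means interval are
accepted as a fallback; remote tail crossings, an artifact of kernel tails,
are rejected and reported as an undeterminable intersection. The `"normal"`
estimator instead solves the quadratic obtained by equating the two normal
log-densities in closed form and is preferable when the binormal assumption
is credible.

## The search

Candidate bounds are the distinct observed scores (not midpoints — a
convention that shifts bounds by at most one observation). For a fixed lower
bound $l$, the cells $TN, FN$ depend only on $l$ and $TP, FP$ only on the
upper bound $u$, and both upper-side cells are nondecreasing in $u$; the
constraint system therefore admits an exact greedy: for each $l$, the
largest $u$ with $TP \le \frac{s}{1-s} FN$ maximizes the interval's subject
count, and the specificity constraint ($TN \le \frac{s}{1-s} FP$) is also
best served by that same $u$. The test suite verifies this search against an
exhaustive all-pairs enumeration on small tied instances.

## Quality reporting

`quality_threshold()` produces the 3×2 decision table (zones below / inside /
above by condition absent / present) and the MCI metrics computed on the
outer zones only. `quality_threshold_uncertain()` reports the
within-interval counts together with two inconclusiveness diagnostics: the
continuity-corrected (Yates) chi-squared test of the balance of the 2×2
below/above-intersection table — the corrected form is fixed by design, as
2×2 balance tables inside the interval have small expected counts — and the
Welch unequal-variance t-test of the class score means inside the interval.
Insignificance supports the interval being truly inconclusive, though with
many subjects inside even tiny differences turn significant, so the mean
difference itself is reported alongside.

## TG-ROC comparator

The nonparametric Two-Graph ROC draws $Se(t)$ and $Sp(t)$ against the
threshold $t$ and takes the largest $t$ with $Se \ge$ `level` and the
smallest $t$ with $Sp \ge$ `level` as the bounds of its Intermediate Range
($Se$ at $t$ is the fraction of positives $\ge t$; $Sp$ the fraction of
negatives $< t$, mirroring the ties-positive call convention used
throughout). For strong tests whose Se/Sp crossing exceeds the level, the
two bounds come out reversed; they are swapped back and flagged rather than
collapsed to a zero-width range, so results remain available for strong
tests. The achieved Valid-Range Se/Sp is always *measured* on the outer
zones rather than assumed equal to the level — for tests of moderate
strength it routinely falls short of it, which is precisely what makes the
comparison with the UI informative.

The Intermediate Range, unlike the UI, has no internal anchor. To make its
within-range CCR/Se/Sp comparable with the within-UI quantities, the same
estimated density intersection is used as its internal cut; when the
intersection falls outside the range these within-range quantities are
undefined and reported as missing.

## The binormal simulation framework

`binormal_model_grid()` defines 27 test models: healthy scores $N(0,1)$
fixed, diseased mean $\mu_1 \in \{3, 2, 1\}$ (descending), diseased sd
$\sigma_1 \in \{0.6, 1, 1.5\}$ (ascending) and prevalence
$\in \{0.5, 0.2, 0.1\}$ (descending), spanning analytic AUCs from 0.995 to
0.711. `run_model()` draws replicates of $n$ subjects with *fixed* class
sizes $\mathrm{round}(n \cdot \mathrm{prev})$ — fixed rather than binomial
so every replicate represents its stated prevalence exactly and Monte-Carlo
variance is reduced — and per replicate fits the maximized-Youden threshold,
the UI and TG-ROC, recording for each: CCR/Se/Sp at the Youden cut, over the
MCI and Valid Range, within the UI and Intermediate Range, the within-range
Welch tests, and the failure indicators (`p_na`: fraction of replicates with
no feasible UI; `p_tg_na`: TG-ROC level unattainable). Means of UI
quantities are taken over found replicates only, and the significant-t
proportions over replicates where the test is defined (both classes at
least 2 inside, positive variance). Per-replicate seeds are derived from the
master seed by a counter (`seed + 100000 * model_id + replicate`) and
recorded, so any replicate can be replayed in isolation.

What the generator emulates — and what it does not: binormal score pairs
cover many practical tests and approximate many more, but real scores can be
skewed, bounded, discrete or multimodal, and real reference standards are
imperfect. Passing the simulation checks therefore demonstrates correctness
of the machinery and the method's behavior *under binormal conditions*, not
a guarantee for arbitrary clinical data. The synthetic clinical fixture
(`make_clinical_fixture()`) likewise reproduces published-style decision
*tables* via deterministic score placement; only its counts are meaningful,
not its score values.

## Numerical choices and degenerate inputs

* Positive call at `score >= threshold` everywhere (ties positive);
  within-interval ties at the intersection go to the lower half. Both are
  conventions the underlying data cannot decide, fixed for reproducibility.
* Ties among optimal single thresholds resolve to the smallest threshold
  after each method's stated secondary criterion (maxSe breaks ties by Sp,
  maxSp by Se).
* `minPvalue` uses the uncorrected Pearson chi-squared on the dichotomized
  2×2 table; degenerate tables (a zero margin) are assigned $p = 1$.
* Feasibility requires every within-interval cell $\ge 1$, keeping
  within-interval Se/Sp well-defined and making *not found* meaningful for
  strong tests. No lower bound is imposed on within-interval Se/Sp.
* Interval bounds are inclusive on both sides.
* Comparisons against the `select` bound use an absolute tolerance of 1e-9
  so integer count ratios sitting exactly on the bound are accepted.

## Problem sizes used in the checks

The packaged tests exercise the Monte-Carlo claims at 100–150 replicates of
$n = 1000$ per model (the full grid at 100 replicates runs in well under a
minute), with exhaustive-oracle comparisons on small instances of at most
50 subjects and 20 distinct scores. The framework itself runs the full
1000-replicate design via `run_grid(reps = 1000)` when a complete
reproduction is wanted.

## Known limitations

* The UI requires a determinable density intersection and non-trivial
  overlap; for very strong tests (AUC ≳ 0.99) up to half the samples admit
  no interval, and the method should then be read as saying "this test has
  almost no inconclusive zone".
* Results beyond binormal scores are not covered by the simulation evidence
  here, although the method itself is rank-based except for the intersection
  estimate.
* The mean *size* of the UI is sensitive to the tie-break rule among
  feasible intervals (subject count, then width, then lower bound); bounds
  and quality metrics are far more stable across reasonable rules than the
  size itself.
* Only two classes are supported, and no cost weighting of error types is
  offered.
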