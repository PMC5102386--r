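# trithresh

Three-way interpretation of diagnostic test scores: *negative /
inconclusive / positive* instead of a single cutpoint.

## Why

Dichotomizing a continuous diagnostic score at one threshold — however the
threshold is chosen — places the cut exactly in the overlap of the two class
distributions, where the score is least informative, and turns near coin
flips into confident diagnoses. `trithresh` is for biostatisticians and
clinical researchers evaluating such scores (biomarkers, assay read-outs,
risk probabilities from a prediction model) who want to (1) identify the
subjects whose scores genuinely cannot support a decision and (2) quantify
how much the accuracy of the remaining decisions improves once those
subjects are set aside.

## The method

The **Uncertain Interval (UI)** is anchored at the intersection $x^\*$ of
the two class densities — the score at which a subject is equally likely to
come from either class. Within a candidate interval $[l, u] \ni x^\*$,
subjects are classified by $x^\*$ itself, giving within-interval counts
$TP, FP, TN, FN$ and

$$Se_{UI} = \frac{TP}{TP+FN}, \qquad Sp_{UI} = \frac{TN}{TN+FP}.$$

The UI is the interval containing the most subjects subject to
$Se_{UI} \le s$ and $Sp_{UI} \le s$ with the selection bound $s = 0.55$ by
default (correct and false calls inside it balanced to odds of at most
1.22:1) and every cell at least 1. Scores outside the UI form the **More
Certain Interval (MCI)**: below called negative, above positive. Also
included:

* the nonparametric **TG-ROC** comparator (Valid / Intermediate Range at a
  pre-selected Se/Sp level, with re-reversal of crossed bounds for strong
  tests),
* seven classical single-threshold criteria (maximized **Youden index**,
  maxSe, maxSp, minPvalue, ROC01, SpEqualSe, fixed),
* trichotomous decision tables with outer-zone CCR/Se/Sp, within-interval
  balance diagnostics (Yates chi-squared, Welch t),
* mixed probability histograms, TG-ROC curves, density/intersection plots,
* a binormal Monte-Carlo framework (27 standard test models crossing
  diseased mean 3/2/1, sd 0.6/1/1.5 and prevalence 0.5/0.2/0.1) comparing
  Youden, UI/MCI and TG-ROC.

## Worked example

A moderately strong test (healthy N(0,1), diseased N(2,1), prevalence 0.5,
n = 1000):

```r
library(trithresh)
d  <- binormal_sample(binormal_model(mu1 = 2, sd1 = 1, prevalence = 0.5),
                      n = 1000, seed = 42)
ui <- find_uncertain_interval(d, select = 0.55)
ui
#> Uncertain Interval: [0.59, 1.32] (intersection 0.9152)
#> 172 subjects inside; within-interval Se 0.548, Sp 0.545, CCR 0.547 (select 0.55)

quality_threshold(d, ui$lower, ui$upper)
#> Decision table (interval [0.59, 1.32]):
#>               Condition
#> Diagnosis        no  yes  Sum
#>   negative      368   42  410
#>   inconclusive   88   84  172
#>   positive       44  374  418
#>   Sum           500  500 1000
#> Outside the interval (n = 828): CCR 0.896  Se 0.899  Sp 0.893

optimal_threshold(d, "youden")
#> Decision threshold (youden): 0.7622
#> Se 0.892  Sp 0.802  CCR 0.847
```

Reading: 172 of 1000 subjects receive the diagnosis "inconclusive" — inside
the interval the correct classification rate is 0.547, barely better than a
coin flip, confirmed by the balance diagnostics
(`quality_threshold_uncertain(d, ui)`: chi-squared 1.14, p = 0.29; Welch
t = −1.26, p = 0.21). For the 828 subjects outside it the CCR is 0.896,
versus 0.847 when all 1000 are forced through the optimal single (Youden)
threshold.

A command-line front end covering the same operations ships at
`inst/cli/trithresh` (`dichotomize`, `ui`, `tgroc`, `simulate`, `plot`,
`fixture`).

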