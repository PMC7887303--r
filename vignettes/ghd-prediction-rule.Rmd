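---
title: "Deriving and validating a high-specificity prediction rule for pediatric GHD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating a high-specificity prediction rule for pediatric GHD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghdrule)
```

## The clinical question and the modelling stance

Growth hormone stimulation tests (GHSTs) remain the diagnostic gold
standard for pediatric growth hormone deficiency (GHD), but they are
invasive and, in neonates or fragile patients, risky. The pipeline in
this package asks: in a child who already meets the auxologic criteria
for testing, can a handful of documented risk factors establish the
diagnosis outright?

The modelling stance is deliberately asymmetric. A false negative is
cheap — the child simply proceeds to the GHST that would have been done
anyway. A false positive is expensive — it means a GHD label and GH
treatment without confirmatory testing. Every design choice below
(missing-value policy, branch pruning, the validation axes) follows from
prioritising specificity over sensitivity, with sensitivity only
required to stay clinically useful (> 0.2).

## Case ascertainment and predictors

A patient is a **case** when the maximal stimulated GH across all test
arms is strictly below the era cut-off: 6.1 ng/ml for tests up to 2011
and 4.7 ng/ml from 2012 on, reflecting a change in the GH assay
standard. The boundary is strict (`4.7` is a control) and the cut-off
table is configurable (`era_cutoffs()`). Patients of 10 kg or more
require two sequential test arms (arginine–clonidine); lighter infants
may have one. The era boundary is implemented as calendar years
(cut-off 6.1 through 2011, 4.7 from 2012) because test dates are only
resolved to years in the cohort schema.

Fifteen dichotomous predictors are derived from raw measurements by
`derive_predictors()`, each with an explicit operational threshold
(e.g. TSH deficiency: free T4 < 0.8 ng/dl with TSH ≤ 10 mIU/l under two
months of age, ≤ 6.5 mIU/l thereafter; severe TBI: Glasgow Coma Scale
≤ 8; cranial radiotherapy: ≥ 18 Gy). All thresholds are strict as
stated. Three-valued logic is first-class at this layer: a missing
input yields a *missing* flag, never a silent `FALSE`. In particular,
pituitary dysgenesis is missing whenever no MRI was performed —
conflating "no MRI" with "normal MRI" would bias the dysgenesis clause.
Two composite predictors resolve early when the known components settle
the outcome: hypogenitalism (two of micropenis, cryptorchidism,
micro-orchidism) can be `TRUE` with one component unknown, and a normal
free T4 excludes TSH deficiency even when TSH itself is unmeasured.

Eligibility screening (`check_eligibility()`) implements the standard
auxologic criteria (severe short stature < −3 SDS, deficit below the
mid-parental channel, short stature with growth deceleration, isolated
low height velocity) and accepts the three sign-based criteria
(intracranial lesion, multiple pituitary deficiency, neonatal GHD
signs) as booleans, because no operational definition exists for them.

## Association panel

Each predictor is tabulated against GHD status as a 2×2 table. Two
denominator policies exist: `full_cohort` (an undocumented exposure
counts as absent — this is how the published margins are constructed)
and `assessed_only`, used for the MRI-defined dysgenesis where the
denominator is the 218 patients actually imaged.

The odds-ratio point estimate is the cross-product ratio `ad/bc`.
Interval methods:

* **Woolf logit** (default for all-positive tables): `exp(log OR ±
  z·√(1/a+1/b+1/c+1/d))`.
* **Haldane-corrected** logit (+0.5 to every cell), usable at zero
  cells.
* **Exact conditional**: tail inversion of the noncentral
  hypergeometric distribution of the `a` cell given all margins,
  implemented by direct normalised enumeration of the support and root
  finding on the log-odds scale. At a boundary table (`a` at the top of
  its support) the corresponding bound is one-sided, so an
  all-cases-exposed predictor yields OR = ∞ with a finite exact lower
  bound and an all-controls-exposed predictor yields OR = 0 with a
  finite upper bound. The implementation is verified in two independent
  ways: the achieved tail probability at each bound equals α/2 by
  longhand enumeration, and the bounds agree with
  `stats::fisher.test` (which inverts the same tails with a coarser
  root tolerance).

The published interval bounds for the zero-cell rows do not correspond
to any single standard method we could identify (conditional exact,
mid-P and Cornfield score inversions all come close on some rows and
not others, and no method is named in the source material), so interval
*bounds* are treated as verification candidates while point odds ratios
are hard test assertions — all fifteen reproduce to the printed
decimal. Association p-values are uncorrected Pearson chi-squared on
one degree of freedom, per the stated analysis plan; display flooring at
"<0.0001" mirrors the published formatting while raw values are kept.
No multiplicity correction is applied across the fifteen predictors, by
design.

## Tree induction

`fit_tree()` grows a C4.5-family tree: multiway nominal splits, split
quality = **gain ratio** (information gain divided by the intrinsic
entropy of the partition sizes; Gini is available as an option), no
post-pruning, and a minimum of two records per node — a candidate split
leaving any non-empty child below the minimum is rejected. The three
anterior deficiencies enter as a single derived feature,
`anterior_deficiency_count` ∈ {0, 1, 2+}; the printed "0 / 1 / ≥1"
categorisation is internally inconsistent and is read as 0/1/≥2,
consistent with the final rule's "two or more" clause.

Numerical and policy choices that the source material leaves open:

* **Tie-break**: among equally good splits, the lowest column index
  wins. This makes the fit deterministic and invariant to row
  permutation (tested).
* **Missing values**: rows missing the candidate attribute are excluded
  from that split's evaluation and routed with the largest child, both
  during induction (so class counts are conserved down every path) and
  at prediction time. Fractional-instance weighting was considered and
  rejected as out of scope.
* **Leaf labels**: majority vote; an exact tie labels the leaf
  `control`, the safe direction.

**False-positive branch pruning** (`prune_fp_branch()`) implements the
specificity-driven refinement: the labelled data are routed through the
tree, every subtree below the root is scored by the false positives its
leaves produce, and the highest-scoring subtree is replaced by a
control leaf. Ties prefer the deepest such subtree — the smallest cut
that removes the same number of false positives, hence the smallest
sensitivity loss. Specificity on the pruning data can only rise and
sensitivity can only fall (tested as an invariant). The iterative
clinician-in-the-loop refinement of the original analysis is not an
algorithm and is not reproduced; its end state is the explicit rule.

A stratified repeated hold-out harness (`cv_tree()`, 20% test fraction
by default) reports per-repeat sensitivity, specificity and accuracy
with their dispersion.

## Ensemble feature relevance

`fit_forest()` fits (by default) 100 gain-ratio trees on bootstrap
resamples with `ceiling(sqrt(p))` features considered per node, and
scores each feature by its split occurrences weighted `1/(1+depth)`,
with depth-0/1/2 counts reported separately. The original analysis
names only the tool used, not its parameters, so these defaults follow
common random-forest practice; accordingly only rank-level statements
are asserted (signal features outrank non-informative ones; same seed,
same report; more trees, stabler ranks). The forest is never used for
prediction.

## The rule layer

`classify_rule()` evaluates the three clauses in order (dysgenesis;
two or more anterior deficiencies; one deficiency plus a qualifying
comorbidity) and reports which clause fired and which comorbidities
qualified. At this layer **missing never satisfies a clause**: the data
layer preserves missingness, the rule layer resolves it against the
patient, because a false positive is the costly error. Two properties
are enforced by tests: monotonicity (setting any flag `TRUE` never
turns a positive decision negative) and missing-robustness (degrading
a `FALSE` to missing never creates a positive). The rule ignores the
five predictors outside its seven inputs, and refuses patients who do
not meet the GHST eligibility criteria — it is only validated inside
that population.

## Evaluation

All proportions carry **Wilson score intervals**, chosen because they
are well-behaved at the boundary (specificity 1, PPV 1) and because
they reproduce the published intervals for sensitivity 61/150
(33.1–48.7), 20/36 (39.6–70.5) and the lower bounds 620/620 (99.4) and
61/61 (94.1) to one decimal. One published bound (the validation PPV
upper limit) matches no single standard interval and is excluded from
hard assertions. The positive likelihood ratio is `sens/(1−spec)`,
reported internally as `Inf` at specificity 1 and formatted as
`">1,000"`. The number needed to test is `1/(PPV+NPV−1)` — this
formula, and no other we tried, reproduces all three published values
(1.21, 1.14, 1.19) from their confusion matrices, which is itself a
test. Metrics with a zero denominator are `undefined`, never 0.

Significance follows the stated validation design: under the null that
a positive rule call is uninformative, each call is a Bernoulli trial
with success probability equal to the cohort prior; the p-value is the
exact upper binomial tail over the rule's positive calls, compared
against α = 1e-5. The exact random variable is one defensible reading
of the described procedure (correct positives among all positives) and
is isolated in `binomial_significance()` so alternative readings are
one call away. The three validation axes are: safety (specificity
≥ 0.99 — "type I error near 0" made operational), usefulness
(sensitivity > 0.2) and significance (p < α).

## The synthetic cohorts

No patient-level data are distributed, so `simulate_cohort()` generates
them. The joint distribution of the fifteen flags is under-determined
by the published margins; it is induced through clinical archetypes
encoded in fixed templates — congenital multiple-deficiency patients
carry dysgenesis, several anterior deficiencies, diabetes insipidus
and neonatal signs together; acquired patients carry tumor,
radiotherapy and chemotherapy; isolated-GHD patients carry little else
— tuned so that every per-predictor case/control margin equals the
published count *and* no control profile satisfies the rule
(reproducing the derivation cohort's zero false positives and the
validation cohort's single false positive, i.e. TP = 61/FP = 0 and
TP = 20/FP = 1). The inconsistency between the validation table's "21
predicted" and the reported 55.6% sensitivity (20/36) plus one
described false positive is resolved in favour of the latter reading.

In `exact_marginal` mode one patient is instantiated per template row,
so the association panel reproduces every published odds ratio exactly
and the seed affects only demographics, auxology and GH peak values. In
`stochastic` mode case status is Bernoulli and profiles are resampled
from the template strata, preserving the between-flag dependence while
all margins fluctuate; conditional rates converge to the template rates
as n grows (tested at n = 100 and n = 10,000).

Continuous variables are sampled from normal distributions whose
median and IQR match the published cohort tables (IQR/1.349 as the SD);
tails are unconstrained because only median and IQR are reported. GH
peaks are uniform draws strictly below the era cut-off for cases and
with at least one arm above it for controls — placeholders with the
correct ascertainment behaviour, not a secretion model. A low height
velocity is filled in where the height deficit alone would not satisfy
any eligibility criterion, since all simulated patients represent
children who *were* tested. What passing tests on these cohorts show is
therefore that the pipeline's logic and calibration are correct — not
that the rule would attain these operating characteristics on new
clinical data, where the joint distribution of risk factors, the
missingness mechanism and borderline GHST results (the described false
positive peaked at 6.71 ng/ml, just above the cut-off) can all differ.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
published cohort sizes (770 and 161 patients) and use reduced ensemble
sizes (10–40 trees) and Monte-Carlo sizes (10,000 patients, 3–10 seeds)
where only directional or convergence claims are being checked; these
sizes were chosen as the smallest that make the checks stable. All
randomness flows through explicit seeds; the pipeline bundle embeds the
seed and a configuration hash, and identical inputs produce identical
bundles.

## Known limitations

* The decision tree's exact confusion matrix on a synthetic cohort is
  not expected to equal the published tree column (74/5/76/615):
  patient-level joint data are unavailable, and the tree sees only the
  template-induced dependence. The direction of the pruning shift and
  the rule's exact confusion matrix are reproduced instead.
* Published confidence bounds for zero-cell odds ratios and the
  validation PPV upper bound could not be attributed to a single
  method; the package's intervals are method-labelled so any
  alternative can be compared explicitly.
* Gonadotropin deficiency is not an input (unascertainable in
  prepubertal patients), and ROC analysis is out of scope because the
  predictors are binary.
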