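---
title: "Methods behind the raads14 package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the raads14 package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raads14)
```

This vignette is the package's own account of the statistical machinery it
implements: the scoring model, the rank-based comparison and ROC toolkit,
the reliability and factor methods, the item-reduction pipeline, and the
synthetic-cohort generator that everything is exercised on. It also records
the numerical conventions and the design choices that were genuinely open.

## The instrument model

A Likert screening instrument here is a fixed-order list of items answered
on an ordered categorical scale. For the RAADS-14 Screen the scale has four
duration-anchored categories scored 0–3, and the total score is the plain
sum over the 14 items, range 0–42. Reverse-formulated items (item 6, "I can
chat and make small talk with people") are included to catch response bias;
their score is the complement $3 - x$ of the forward score, the only mapping
under which a higher total uniformly means more autistic traits. Subscales —
mentalizing deficits (items 1, 4, 9, 11, 12, 13, 14), social anxiety (3, 5,
6, 8) and sensory reactivity (2, 7, 10) — partition the items, so subscale
scores add up to the total by construction; the package asserts this
partition on every scored record. Items 1–5 double as a rapid short form
(0–15).

Two record-validity rules mirror standard questionnaire hygiene:

* **Excess missingness** — more than `max_missing = 4` unanswered items
  invalidates the record.
* **Straight-lining** — answering every item with the same category is
  impossible to produce attentively when a reversed item is present, so
  such records are flagged, provided at least two items were answered and
  the instrument contains a reversed item. Missing answers are ignored by
  this check. When both rules fire, excess missingness is reported, in the
  order the rules are stated.

**Missing items in retained records.** How up-to-four missing items should
enter the total is not fixed by the instrument's published description. The
default scores them 0 — deterministic, conservative (a missing answer can
only lower the total, never push a respondent over the cut-off) — and the
count is surfaced as `n_missing`. Prorating (scaling each scale sum by
`k / n_answered`, rounded) is available via `missing = "prorate"`; it is
applied per subscale and the total is the sum of the prorated subscales, so
the partition invariant survives prorating.

## Rank comparisons, ROC and the cut-off rule

Group contrasts use the Mann–Whitney $U$ test throughout, because totals on
a short bounded integer scale are heavily tied and far from normal. Ranks
are mid-ranks; the normal approximation uses the tie-corrected variance
$$\sigma_U^2 = \frac{n_1 n_2}{12}\Big((N+1) - \frac{\sum_t (t^3-t)}{N(N-1)}\Big)$$
and no continuity correction (with the tie structure of 0–42 integer data
the correction is not well defined and SPSS-style output, the reference
style for this literature, omits it). The effect size is $r = |z|/\sqrt N$.

Two $U$ orientations coexist in applied reports. The headline `u` follows
the smaller-side convention $\min(U_1, U_2)$, which is what statistical
packages print; the orientation-specific statistic
`u_cases_lower` = #\{case < control\} + ties/2 is returned alongside because
it is the one tied to the ROC area:
$$\mathrm{AUC} = 1 - \frac{U_{\text{cases lower}}}{n_1 n_2}.$$
The empirical ROC sweeps the rule "score ≥ t" over all distinct scores and
integrates by trapezoid over (1 − specificity, sensitivity); with mid-rank
ties the trapezoidal area and the $U$-based area are *identical*, not just
close, and the test suite asserts agreement to $10^{-9}$ on a thousand
random tied datasets.

**Cut-off selection.** The screen's rule is the lowest score whose
true-positive rate is at least 93%. Because sensitivity is non-increasing
in the threshold, every threshold below a qualifying one also qualifies,
so "lowest score" needs a tie rule. The default returns the *largest*
qualifying threshold — the most specific cut-off still retaining the
required sensitivity, which is the only reading under which a published
cut-off of 14 (rather than 0) can emerge from the rule; the literal
smallest-qualifying variant is exposed as `rule = "lowest"` for
completeness. `select_cutoff()` is verified against exhaustive search over
all integer thresholds on every random instance in the suite. Note that on
cohorts drawn at the phase-III moments alone the selected cut-off can sit
above 14: the published 14 was selected on the combined phase II + III ASD
sample, whose lower-scoring phase-II arm pulls sensitivity at 14 down to
just above the constraint.

## Reliability and item statistics

Cronbach's alpha uses the variance form
$\alpha = \frac{k}{k-1}\big(1 - \sum_i s_i^2 / s_T^2\big)$ with $n-1$
denominators, and is reported as undefined (with a warning) when the total
has zero variance. Corrected item–total correlations correlate each item
with the sum of the *other* items. For two standardized items the suite
checks the closed form $\alpha = 2r/(1+r)$ to $10^{-12}$, and on one-factor
data with loading 0.7 the Spearman–Brown value $k\bar r/(1+(k-1)\bar r)$
within ±0.02 at $n = 2000$.

The discrimination index used for item selection is the product of the
point-biserial correlation between item score and case indicator (the
"Pearson effect size" of the group difference — the pooled-variance
point-biserial is our definition, since the variance convention is not
otherwise pinned down) and the corrected item–total correlation within the
item's original domain. Zero-variance items are flagged degenerate rather
than given an index.

## Factor analysis

Construct validity is probed by exploratory factor analysis on the item
correlation matrix using principal-axis factoring: squared multiple
correlations initialise the communalities, and the reduced matrix is
re-eigendecomposed with the implied communalities fed back until they move
by less than $10^{-6}$ (at most 100 iterations). Factors are ordered by
eigenvalue and each factor's share of variance is $\lambda_i/k$. Varimax
rotation (on normalized loadings) is applied by default — the published
analysis is silent on rotation, and varimax is the default a practitioner
would reach for — with the unrotated solution always retained. A sign
convention (largest |loading| positive per factor) makes solutions
reproducible.

The number of factors is a scree-plot judgment in the source analysis; the
package parametrizes it: `n_factors = "auto"` keeps eigenvalues of the
initial reduced matrix at or above their mean, and `evaluate_final()`
defaults to 3 for this instrument, the scree choice. Note one consequence
of principal-*axis* (rather than principal-component) extraction: for pure
white-noise items the reduced-matrix eigenvalues are near zero, so all
variance shares are near zero and mutually equal — they do not approach the
$1/k$ that component eigenvalues would give.

Degenerate inputs: a singular correlation matrix falls back from SMC to
maximum-absolute-correlation starting communalities and is flagged
`degenerate`; zero-variance items are a hard error naming the items.

## The three-phase reduction pipeline

1. **Quota-constrained selection** (`phase1_select`): within each original
   domain of the full bank, items are ranked by discrimination index
   computed on cases versus *non-psychiatric* controls, and the per-domain
   quotas (bundled default 4/2/8/4 over circumscribed interests, language,
   social relatedness, sensory motor = 18) keep the bank's domain
   proportions for content validity.
2. **Per-item ROC pruning** (`phase2_prune`): in a *psychiatric* cohort
   (cases vs other psychiatric records — the population the screen must
   work in), each item's individual AUC is computed and the `n_drop = 4`
   weakest items are removed. "Discriminatory power" is summarised by AUC,
   the measure the ROC framework itself supplies. A constant item gets AUC
   0.5 by convention.
3. **Re-ordering** (`reorder_items`): the five items with the highest AUC
   go first, enabling a leading short form; the remainder are interleaved
   across subscales by a deterministic greedy rule (pick the subscale with
   most items left that differs from the previous pick; ties by subscale
   first-appearance; within subscale ascending id). The published
   instrument's exact mixing rule for the tail is not fully specified;
   this interleave is one admissible deterministic realization, chosen so
   that no two adjacent tail items share a subscale whenever feasible.

All tie-breaks anywhere in the pipeline resolve by ascending original item
id and are logged in the report's audit tables, so any stage can be
re-checked from the report alone. The pipeline is a pure function of its
input cohort: identical input gives byte-identical reports.

`evaluate_final()` assembles the full validation battery — per-group
summaries over valid records, case-vs-control rank tests with effect
sizes, ROC/AUC per control group, operating points at the total and
short-form cut-offs, alpha per group and subscale, and the factor solution
computed on the cohort *excluding* the case group: when cases endorse
nearly everything, their inclusion collapses the correlation structure to
a single factor, and the substantive three-factor structure only emerges
among controls.

## The synthetic-cohort generator

There is no deposited response-level dataset, so the generator is the test
bed for every analysis. Each subject draws a general trait
$G \sim N(\mu_g, \sigma_g^2)$ for their diagnostic group plus three
standardized subscale factors with pairwise correlation 0.5 (configurable);
the latent input to item $j$ is
$$\theta_j = s_j\big(G + \sigma_g\sqrt{w_j/(1-w_j)}\,F_{s(j)}\big)
           + \sqrt{1-s_j^2}\,\varepsilon_j,$$
so `loading` $w_j$ (default 0.3) is the subscale factor's share of
within-group latent variance and `signal` $s_j \in [0,1]$ lets tests plant
pure-noise items ($s_j = 0$). Categories follow a cumulative-logit graded
response model, $P(X_j \ge k\,|\,\theta_j) =
\mathrm{logit}^{-1}(a_j(\theta_j - b_{jk}))$, with slopes 1.4–1.9 and
threshold triplets spread across the latent range with narrow 0.3 gaps, so
the two intermediate duration categories are emitted but are rarer than
the extremes — for all analyses only the 0–3 score matters, the category
semantics are cosmetic. Skew is induced purely by trait location relative
to the thresholds (floor and ceiling effects), not by any ad-hoc
transform: the ASD profile sits near the ceiling (left skew), the
non-psychiatric profile near the floor (right skew).

Reversed items are driven by the same latent in *scored* space — the model
draws the scored value and emits the complementary raw category — the
standard item-response treatment of reverse-coded items. A consequence
worth stating: a degenerate floor cohort (`trait_sd` → 0, extreme negative
mean) scores 0, not the 3 that a raw "never true" straight-liner scores,
because the floor respondent answers the reversed item in the
trait-consistent direction.

Contamination is applied last: with probability `straight_line_rate`
(default 0.025) a record is overwritten with one uniformly drawn category
for all items, and each answer is independently blanked with
`missing_rate` (default 0.003). The defaults are of the order of the
exclusion counts reported for clinical questionnaire collections of this
kind (a few percent straight-liners, a handful of excess-missing records
per thousand).

**Calibration.** The four group profiles are trait means/SDs frozen from
`calibrate_profiles()`: a deterministic coarse grid over $(\mu, \sigma)$
followed by two local refinements, minimising the squared distance between
simulated total-score mean/SD (common random numbers, fixed internal
stream, 4000 subjects per evaluation) and the published moments
30.8 ± 8.6 (ASD), 15.4 ± 9.3 (ADHD), 12.6 ± 9.3 (other psychiatric),
3.9 ± 4.6 (non-psychiatric). The routine stays exported and tested; the
frozen values reproduce all eight moments within 1.0 in the suite. Default
group sizes are the validation-phase sample sizes (77/301/69/590).

**What the generator does and does not emulate.** It reproduces the group
locations, spreads, skew directions, ordering of medians, a plausible
reliability level, and a recoverable subscale structure; contamination
exercises the validity filters. It does *not* claim item-level fidelity:
true item parameters are unpublished, comorbidity structure, age and
gender effects are absent, and the non-psychiatric group is simply a
low-trait group rather than a distinct population. Passing tests therefore
demonstrate that the *methods* behave correctly under known ground truth —
not that the instrument's clinical properties are re-established on real
patients.

## Problem sizes and runtime choices

The suite runs moment-calibration checks at 2000 subjects per group, skew
checks at 5000, factor-recovery at 3000, planted-null pruning across 20
replicates of 2000 subjects, and the ROC/U identity over 1000 random tied
datasets — sizes at which the stochastic assertions have comfortable
margins while the whole suite stays fast on a single CPU. The acceptance
script draws 10,000 totals, the size at which a ±0.02 band on a proportion
near 0.97 is essentially deterministic (binomial SD ≈ 0.0017).

## Known limitations

* The effect-size convention $r = |z|/\sqrt N$ does not reproduce every
  published table value exactly (some rows are consistent only with other
  $N$ choices); the package computes the formula and does not
  reverse-engineer per-row denominators.
* Exact small-sample $U$ distributions and confirmatory factor analysis /
  IRT estimation are out of scope; the graded-response model lives in the
  generator only.
* Prorated missing-item scoring rounds per subscale, so a prorated total
  can differ by a point from prorating the raw total directly; the
  partition invariant is kept deliberately.
* `straight_line` detection requires a reversed item; instruments without
  one accept uniform response patterns as valid, which is the correct
  behaviour but worth remembering when defining custom instruments.
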