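---
title: "Designing integer scoring systems with honest score-class uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing integer scoring systems with honest score-class uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bootscore)
library(dplyr)
```

## The problem

Clinical scoring systems predict an adverse outcome by summing a handful of
integer points: each selected risk factor contributes its weight when the
patient lies on its risk side. The appeal is that a score can be computed at
the bedside; the weakness is attaching a *trustworthy outcome probability*
to each score. The observed morbid fraction of a score class is a point
estimate from a finite training sample, often a small one for the highest
scores, and reporting it without uncertainty invites over-interpretation.

`bootscore` implements the full design loop for such systems on a
patient-by-variable cohort table with a binary outcome (1 = morbid):

1. **Split** — morbid and normal patients are allocated to training and
   testing halves separately, so both halves share the same outcome
   prevalence; comparability of every candidate variable across the halves
   is then checked (Fisher's exact test for dichotomous variables; for
   continuous ones a two-sample z-test when Shapiro-Wilk accepts normality
   in both halves at 0.05, otherwise Mann-Whitney).
2. **Dichotomize and screen** — every continuous candidate is cut at the
   point of its ROC curve closest to the (sensitivity, specificity) = (1, 1)
   corner, searching all midpoints between consecutive distinct values in
   both risk directions; intrinsically binary candidates are oriented so the
   risk-positive level codes 1. A candidate passes the screen when the lower
   bound of the 95% Woolf confidence interval of its odds ratio exceeds 1.
3. **Select** — a forward stepwise algorithm enters, at each step, the
   action maximizing the training AUC (Mann-Whitney form, ties counted one
   half). Already-entered variables remain candidates: re-entering one
   increments its integer weight, which is how a predictor earns a weight of
   two or more. A deliberately *soft* stopping rule — stop when the
   cumulative AUC gain over five consecutive steps falls below 0.01 — keeps
   the model growing past the first plateau so that enough score classes
   exist for probability estimation.
4. **Quantify** — for every score class, the 95% confidence interval of the
   morbid fraction is estimated by the bias-corrected and accelerated (BCa)
   bootstrap with B = 1000 whole-cohort resamples.
5. **Pool** — adjacent classes with overlapping intervals (or classes
   holding under 2% of training patients) are merged, and intervals and
   discrimination are re-estimated for the coarser system.

The final choice of step remains a judgment call made on the testing curve;
`best_step()` proposes the earliest step with maximal test AUC, and every
intermediate model is retained.

## The score and its estimators

The patient score is \(s = \sum_{i=1}^{d} \lambda_i s_i\), where \(s_i\) is
the integer weight of the \(i\)-th selected binary predictor, and
\(\lambda_i \in \{0, 1\}\) indicates whether the patient's raw value lies on
the risk side of that predictor's cutoff (`at-or-above` or `below` for
continuous variables, a risk level for intrinsic ones). Scoring a patient
with any missing selected predictor is refused rather than imputed — the sum
is undefined without all of its terms.

AUC is computed in its rank form: the probability that a random morbid
patient outscores a random normal one, ties counted one half. This is exact
for heavily tied integer scores and equals the trapezoidal area under the
empirical ROC curve.

The odds-ratio screen uses the Woolf (logit) interval,
\(\exp(\ln \mathrm{OR} \pm z_{0.975}\sqrt{1/a + 1/b + 1/c + 1/d})\), with
the Haldane-Anscombe +0.5 correction applied to all four cells whenever one
is zero. "Significantly greater than 1 at p < 0.05" is operationalized as
the 95% interval lying entirely above 1, the equivalent test.

## The BCa bootstrap for score-class proportions

For a class \(c\), the statistic is the morbid fraction among the patients
of a resampled cohort that fall in \(c\). Design choices that matter:

* **Resampling unit** — the whole training cohort, not the class: class
  membership is recomputed inside every replicate, so the variability of
  class *sizes* propagates into the intervals. One seeded stream of B
  resample index vectors is shared across all classes, so every class
  statistic is evaluated on the same replicates.
* **Empty replicates** — a replicate that contains no patient of a class is
  dropped *for that class* and the effective replicate count `B_effective`
  is reported; the package warns below 0.9 B and refuses below 0.5 B rather
  than silently degrade a sparse top class.
* **Bias correction** — \(z_0 = \Phi^{-1}\big[(\#\{\theta^* < \hat\theta\} +
  \tfrac12 \#\{\theta^* = \hat\theta\})/B_\mathrm{eff}\big]\). The midrank
  convention is essential here: proportions of resampled integer classes are
  heavily tied, and a strict "less than" count would bias \(z_0\) downward.
  A fraction of exactly 0 or 1 is clamped to \(1/(2B_\mathrm{eff})\) from
  the boundary so \(z_0\) stays finite.
* **Acceleration** — the leave-one-patient-out jackknife over the full
  training sample, \(a = \sum(\bar\theta_{(\cdot)} - \theta_{(i)})^3 \big/
  6\big[\sum(\bar\theta_{(\cdot)} - \theta_{(i)})^2\big]^{3/2}\), with
  \(a = 0\) when the denominator vanishes (for a class proportion the
  jackknife values have closed form, so this costs nothing).
* **Quantile rule** — interval endpoints are *actual replicates*: the sorted
  estimate of rank \(\lceil \alpha B_\mathrm{eff} \rceil\) (a small
  numerical fuzz absorbs floating-point error in the product, e.g.
  `0.025 * 1000` exceeding 25 in double arithmetic). With \(z_0 = a = 0\)
  the BCa interval therefore reduces *exactly* to the simple percentile
  interval, a property the test suite asserts on arbitrary distributions.

The defaults — B = 1000 resamples, 95% level — follow the standard empirical
guidance that a thousand resamples suffice for bootstrap confidence
intervals.

## Pooling overlapping classes

Overlap is binary and closed: two adjacent intervals overlap when
\([l_i, h_i] \cap [l_{i+1}, h_{i+1}] \neq \emptyset\), a shared endpoint
counting as overlap (conservative toward pooling). The greedy strategy works
from the top of the score range downwards because that is where classes are
sparse: undersized classes (< 2% of training patients by default) merge into
their lower neighbour first, then the highest overlapping adjacent pair is
merged; intervals are re-estimated after every merge with the same seed.
Pooled classes are labelled by their range, the top one open-ended
(e.g. `>=5`). A `manual` strategy applies a user-written plan verbatim,
because pooling by inspection is a legitimate clinical judgment the package
should replicate, not displace.

One subtlety: with ties counted one half, merging two adjacent classes
lowers the class-rank AUC exactly when the higher class has an observed
morbid fraction at least as large as the lower one. When sampling noise
inverts two near-equal-risk classes — the very situation that motivates
pooling — a merge can *raise* AUC by a hair. The package therefore reports
AUC before and after pooling and makes no monotonicity promise; in practice
the change is well under 0.02 in the regimes the tests exercise.

## The synthetic cohort generator

Because real ICU cohorts of this kind are not publicly deposited, the
package ships a generator whose defaults emulate the structure the method
assumes, with every ground-truth parameter exposed:

* five planted binary risk indicators named after familiar CABG morbidity
  predictors, with prevalences 21.3% (O2ER), 13.6% (Card-ID), 21.3% (PVD),
  8.3% (EM) and 40.9% (CPBt);
* outcome drawn as Bernoulli(\(\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j
  x_j)\)) with unit effects \(\beta = 1\) (odds ratio ≈ 2.7, typical of
  reported morbidity predictors) and a double-strength \(\beta = 2\) for
  O2ER, so the true scoring weights are (2, 1, 1, 1, 1);
* \(\beta_0\) calibrated so the *population* outcome prevalence is exactly
  20.7%. Since the planted indicators are independent, that prevalence is a
  finite sum over the \(2^d\) indicator profiles, so the calibration is done
  by deterministic root-finding on the exact expression rather than by
  Monte-Carlo simulation — exact, seed-free and instantaneous for
  \(d \le 20\) (beyond which enumeration is refused);
* O2ER and CPBt are carried by continuous variables: the value is the
  intended cutoff (40 and 2 h) plus a half-normal offset on the indicator's
  side, so the drawn indicator and the dichotomized carrier agree exactly
  and the intended cutoff is the corner-optimal dichotomization in
  expectation, with the offset scale controlling how sharply it can be
  recovered;
* 20 noise variables (alternating binary and Gaussian) independent of the
  outcome, and default n = 1090.

`true_class_probabilities()` returns the exact \(P(\text{class})\) and
\(P(\text{outcome} \mid \text{class})\) by the same enumeration, giving the
test suite an analytic oracle for coverage and recovery checks.

What the generator deliberately does *not* emulate: correlation between risk
factors (an optional coupling was considered and left out of the defaults
since no correlation structure is reported for such cohorts), missingness,
measurement drift, or physiologic time dynamics. Passing tests on this
generator therefore demonstrate the *statistical machinery* — calibration of
the intervals, recovery of planted structure, determinism — not performance
on any real ICU population.

## Numerical and degenerate-input choices

* Ties in corner distance prefer higher sensitivity (catching morbid
  patients), then the lower cutoff, then the `at-or-above` direction.
* Ties between forward-selection actions prefer entering a new variable
  over incrementing a weight (parsimony of weights), then alphabetical
  order; AUC equality is judged at 1e-12.
* The window rule cannot fire before a full window exists: selection stops
  at the first step \(t > w\) with \(\mathrm{AUC}(t) - \mathrm{AUC}(t - w)
  < 0.01\); a step with no strictly positive increment stops selection
  immediately (`no-improvement`).
* Constant candidate variables are screened out with a reason, never fatal;
  a constant variable reaching `closest_corner_cutoff()` directly is an
  error ("no ROC curve").
* Missing values: screening is complete-case per variable; forward
  selection drops (with a warning) rows missing any screened candidate;
  scoring a patient with a missing selected predictor is an error.
* Shapiro-Wilk is defined for 3–5000 values; larger samples are thinned to
  an even grid of 5000 order statistics, deterministically, and samples too
  small or constant are routed to Mann-Whitney.
* An identity class plan uses the score values observed in training (one
  class each, ranges stretched to cover `0..max_score`); a plan naming a
  class that no training patient reaches is rejected, since its proportion
  is undefined.

## Problem sizes used by the checks

The packaged checks run at deliberately moderate scale: interval coverage is
assessed on 1000 simulated cohorts of n = 200 with B = 1000 (and the
per-class variant on 120 cohorts of n = 545 with B = 600); planted-model
recovery uses 20 cohorts of n = 2000; pooling behaviour uses 20 cohorts of
n = 1200 with B = 1000. These sizes give Monte-Carlo standard errors
comfortably inside the stated tolerances (e.g. ±0.7 points for a 95%
coverage estimate over 1000 replicates) while keeping a full run in the
order of a minute.

## Known limitations

* The screen tests each candidate marginally; confounded candidates can all
  pass, and the greedy forward search makes no optimality claim beyond each
  single step.
* Corner-cutoff selection and screening reuse the same training data, so
  continuous noise variables pass the screen more often than the nominal 5%
  (the cutoff is optimized before testing). The held-out test set exists
  precisely to absorb this optimism.
* BCa's second-order accuracy is asymptotic; for classes of a handful of
  patients the interval is honest mainly through `B_effective` bookkeeping,
  and such classes are exactly the ones the pooling step exists to remove.
* Bootstrap resampling treats patients as exchangeable; clustered or
  time-ordered admissions violate that silently.
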