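---
title: "The Erdodi Index model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Erdodi Index model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eindex)
```

## The model

Performance validity is treated here as an inherently continuous construct
observed through several noisy, coarse indicators. Each embedded validity
indicator (EVI) contributes an ordinal *level of failure* in 0–3, defined by
three increasingly conservative cutoffs on its native scale: level 1 at the
most liberal defensible cutoff (specificity at least .84 against an external
criterion), level 2 near a 10% base rate of failure, level 3 near a 5% base
rate. The Erdodi Index (EI) is the unweighted sum of the k component levels,
and its total is trichotomized into **Pass**, **Borderline**, and **Fail**.
For the standard five-component battery (EI-5) the bands are ≤ 1 / 2–3 / ≥ 4.

Two assumptions are worth making explicit. First, summing unweighted levels
assumes the components are roughly exchangeable carriers of validity
evidence; no component dominates by construction. Second, the trichotomy
acknowledges that intermediate totals (two or three marginal failures, or
one soft and one hard failure) are genuinely indeterminate: the Borderline
band is a legitimate third outcome, and it is *excluded* from any analysis
that needs a dichotomous Pass/Fail, rather than forced into either side.

The Fail line at ≥ 4 has a combinatorial reading that the package verifies
by brute force (`enumerate_fail_combinations()`): over all $4^5$ level
vectors, the minimum number of components failing *only at level 1* that
reaches Fail is four, and the minimum failing *only at level 2* is two. The
bands are configurable in `battery_config()` rather than hard-coded, because
alternative Fail cutoffs (e.g. ≥ 3, which is already quite specific) are a
live calibration question for new batteries.

## Recoding: boundaries, grids, and gap closure

A component declares a failure direction and cuts $(c_1, c_2, c_3)$.
For a `low_fails` indicator the level is

$$\mathrm{level}(x) = [x \le c_1] + [x \le c_2] + [x \le c_3],$$

and the mirror image with $\ge$ for `high_fails`. The failing comparison is
always **inclusive** of the printed threshold ("≤ 4", "≥ 5"), which matches
how such cutoff tables are published.

Published level bands for continuous scales are sometimes printed on the
score grid (e.g. figure-copy bands of "25.5–29.0" and "22.5–25.0" on a
half-point grid), which leaves the open interval between grid points
formally unassigned. The package closes those gaps with one rule: when a
component declares a `granularity`, off-grid raw scores are snapped to the
nearest grid point before comparison, and an exact midpoint resolves
*toward the failure direction* — consistent with the inclusive-threshold
convention, a boundary case never escapes a level it would reach on the
grid. On-grid scores are untouched, so the formula above holds verbatim for
every score that can actually be observed. Example: a figure-copy score of
25.25 snaps to 25.0 and recodes to level 2.

```{r}
rcft <- ei5_battery()$components$RCFT_Copy
recode_score(c(25.5, 25.25, 25.0), rcft)
```

Missing component scores are an error by default: the EI was calibrated on
fully administered batteries and no prorating rule exists for partial ones.
An explicit `missing_policy = "complete_case"` drops incomplete rows and
reports the count; nothing is ever prorated. Raw scores are consumed on
whatever metric the cutoffs are calibrated in (age-corrected scaled scores,
raw counts); the package performs no norm conversions.

## Criterion groupings

Free-standing criterion PVTs are consumed as externally supplied Pass/Fail
labels — their internal scoring is proprietary and not reimplemented. The
G-3 composite of the three Green-family tests is: Pass with zero failures,
Fail with two or more, and *Indeterminate* with exactly one (a single
failure is insufficient evidence; these cases are excluded from dichotomous
grouping, and `g3_dichotomy()` offers the ≥ 1 and ≥ 2 variants for
sensitivity analyses). The one criterion rule that *is* computed from
subscales is the WMT trichotomy, whose rule is public: Pass if Immediate
Recognition, Delayed Recognition, and Consistency all exceed 85.0%,
Borderline if none is below but at least one equals it, Fail if any is
below. Inputs are compared after rounding to one decimal, mirroring the
printed "85.0%" convention, so 85.04% counts as equal rather than above.

TOMM-1 dichotomization goes through the generic cutoff machinery with
`fail_direction = "at_or_below"` (`tomm1_fail()`). Published sources
disagree on the Fail cutoff — ≤ 42 in one summary table, ≤ 43 in another of
the same calibration literature; the package defaults to ≤ 42 and keeps the
cutoff as an explicit argument so the alternative is one keystroke away and
the choice is visible in the caller's code.

## Diagnostic accuracy conventions

All computation is at full precision; display rounding is centralized in
`fmt_prop()` (round half away from zero, the convention of printed clinical
tables — note base R's `round()` differs). Metrics follow the standard
formulas: sensitivity $tp/(tp+fn)$, specificity $tn/(tn+fp)$, overall
correct classification $(tp+tn)/N$, and the base rate of failure
$(tp+fp)/N$, which upper-bounds the false-positive rate. A cutoff sweep
over a scalar index is exactly monotone: sensitivity non-increasing and
specificity non-decreasing as the cutoff grows more conservative, an
identity the test suite asserts rather than samples.

AUC is the Mann–Whitney probability that a random criterion-positive case
scores more extremely (in the failure direction) than a random negative,
ties credited one half; it is computed from midranks and equals both the
exhaustive pairwise count and the trapezoidal area under the empirical ROC
(both kept as independent oracles in the tests). The standard error and 95%
interval use the Hanley–McNeil normal approximation: it is deterministic,
closed-form, and matches what the common statistics packages report at
cohort sizes in the hundreds. Bootstrap or DeLong intervals would be
defensible alternatives; interval width is not load-bearing anywhere in the
package, so the simplest well-known choice wins.

Cross-range likelihood ratios are quotients of band-wise base rates of
criterion failure (Fail over Pass, etc.), so $LR_{F/P} = LR_{F/B} \times
LR_{B/P}$ holds exactly at full precision and only approximately after
display rounding. Effect sizes follow the conventions of the calibration
literature: $\Phi^2 = \chi^2 / N$ for contingency tables (with $N$ the n
actually underlying the table — subsample analyses carry their own n), and
Cohen's $d$ with the **average-variance** denominator
$\sqrt{(s_1^2+s_2^2)/2}$. The df-pooled variant is available behind
`pooled = TRUE`; the average-variance form is the default because it is the
one that reproduces the published worked values for this literature, where
group SDs are systematically unequal (invalid performance inflates
variability, so df-pooling would weight the larger group's smaller SD).

One known reporting ambiguity is documented rather than resolved: published
overall-correct-classification cells for index-versus-composite sweeps
cannot always be reconstructed from the printed sensitivity, specificity,
and group sizes under the stated OCC formula, because the denominator
composition (whether indeterminate criterion cases are counted) is not
stated. The package always applies the stated formula over the
criterion-included cases.

## The synthetic cohort generator

No clinical data ship with the package; `simulate_cohort()` exists so the
scoring and diagnostics pipeline can be tested end-to-end against a known
ground truth. The generative model is deliberately simple and is *invented
for testability* — it emulates the broad statistical structure such
batteries show, not any real dataset:

* A latent binary credibility state: non-credible with probability
  `prevalence` (default .20, mid-range for mixed clinical/forensic
  referral streams).
* One shared Gaussian severity factor per examinee. Component $j$ observes
  $z_{ij} = \sqrt{\rho}\, F_i + \sqrt{1-\rho}\,\varepsilon_{ij}$ (default
  $\rho = .30$), scaled to the component's native mean and SD and oriented
  toward its failure direction — so indicators co-fail the way embedded
  indicators do, without being redundant.
* Non-credible responding is a mean shift of `noncredible_shift` SD toward
  failure (default 1.5, in line with the effect sizes free-standing PVTs
  show between credible and non-credible groups) **plus** an SD inflation
  (`sd_multiplier`, default 1.5), reflecting the replicated finding that
  invalid performance is more variable, not just worse.
* Scores are then clipped to each component's valid range and snapped to
  its grid. Credible-state defaults sit where a clinical sample sits
  (e.g. Coding ACSS 10 ± 3, figure copy 32 ± 3.5, recognition hits
  14.5 ± 1.5).
* Criterion PVT fail flags are drawn per test from stated operating
  characteristics conditional on the latent state (defaults: sensitivities
  .70–.80, specificities .92–.95, putting simulated base rates of failure
  in the mid-teens to low twenties of percent). Setting a criterion to
  sensitivity = specificity = 1 makes its flag equal the latent state
  exactly, which the tests exploit: band-wise criterion failure rates then
  equal band-wise planted prevalence identically.
* Referral-source labels follow a realistic referral mix (IME 45.8%,
  clinical 30.2%, medico-legal 9.5%, workplace compensation 8.8%), with
  incentive status derived from them.

What the generator does **not** emulate: demographic confounding (age and
education gradients), diagnosis-specific score profiles, genuine severe
impairment that fails PVTs for non-motivational reasons, floor effects
beyond simple clipping, and any dependence of the criterion PVT errors on
each other or on the embedded indicators beyond the latent state. Passing
the recovery tests therefore shows the pipeline is internally coherent —
signals planted under the model's own assumptions are recovered — not that
the index achieves any particular accuracy in real cohorts.

`recovery_report()` runs the full pipeline against the latent truth:
AUC of the total, operating characteristics at the Fail threshold,
band-wise planted prevalence, and the band-wise criterion base-rate table.

```{r}
coh <- simulate_cohort(sim_params(n = 452, seed = 7))
rep <- recovery_report(coh)
round(c(auc = rep$auc$auc, rep$band_prevalence), 3)
```

## Numerical and testing choices

* Determinism: the generator seeds locally and restores the RNG state, so
  identical parameters give identical cohorts without disturbing the
  caller's stream.
* Degenerate inputs fail loudly: empty cohorts score to empty results, but
  a single-class criterion, a zero denominator base rate, an empty band, or
  an out-of-range total are errors, never silent `NaN`s.
* Enumeration is guarded at k ≤ 10 ($4^{10}$ ≈ 10⁶ vectors), far above any
  battery in practical use.
* Test problem sizes: property suites run on dense grids and cohorts of
  60–120; simulation recovery uses one null cohort of 5,000, a shift grid
  at 2,000 with common random numbers, and an exact-criterion cohort of
  2,000. The full suite runs in a few seconds.

## Limitations

The package evaluates and aggregates validity indicators; it does not score
the underlying instruments, convert norms across test editions, or decide
what a Borderline profile means clinically. Likelihood ratios computed from
band-wise base rates inherit the criterion's imperfections — the criterion
PVTs are themselves fallible detectors, so "criterion failure" is not
ground truth in real data, and base rates of failure only upper-bound
false-positive rates. Cutoff calibration for new components (choosing
$c_1, c_2, c_3$ for a new EVI) is supported by the sweep machinery but is a
judgment the user must make against their own criterion data.
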