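# eindex

Multivariate performance validity assessment with the Erdodi Index (EI).

## The problem

Neuropsychological test interpretation assumes the examinee performed
credibly. Performance validity tests (PVTs) check that assumption, and the
modern consensus is to combine *several* of them rather than trust any single
cutoff. Embedded validity indicators (EVIs) — validity cutoffs carved out of
ordinary ability tests such as Digit-Symbol Coding or the Rey figure copy —
make this practical, but each EVI has low sensitivity on its own and a
battery of them needs a principled aggregation rule.

The Erdodi Index answers that need by capturing both the **number** and the
**extent** of validity-indicator failures. Each of *k* components is recoded
onto an ordinal failure scale using three increasingly conservative cutoffs
(c₁, c₂, c₃):

| level | meaning | calibration |
|---|---|---|
| 0 | passed the most liberal cutoff | — |
| 1 | liberal failure | first cutoff with specificity ≥ .84 |
| 2 | conservative failure | base rate of failure ≈ 10% |
| 3 | ultra-conservative failure | base rate of failure ≈ 5% |

The index total is the unweighted sum, EI = Σᵢ levelᵢ ∈ {0, …, 3k}, and is
trichotomized: for the standard five-component EI-5, **Pass** ≤ 1,
**Borderline** 2–3, **Fail** ≥ 4 (the Borderline range is excluded from any
dichotomous criterion analysis). Exhaustive enumeration of the 4⁵ level
vectors shows why ≥ 4 works as the Fail line: it takes at least four
level-1 failures, or at least two level-2 failures, to reach it.

The package provides, for this model:

* a configurable cutoff engine (`component_spec()`, `battery_config()`,
  `recode_score()`, `score_cohort()`), with the standard EI-5 battery
  shipped as the default (`ei5_battery()`, or YAML under `inst/extdata/`);
* criterion groupings from free-standing PVTs: the G-3 composite of the
  Green-family tests (`g3_outcome()`, `g3_dichotomy()`), the WMT subscale
  trichotomy (`wmt_trichotomize()`), joint two-classifier outcomes
  (`joint_outcome()`);
* diagnostic accuracy machinery: confusion metrics and cutoff sweeps
  (`roc_sweep()`), nonparametric AUC with Hanley–McNeil intervals
  (`auc_mann_whitney()`), base rates of failure and cross-range likelihood
  ratios (`range_br_analysis()`, `value_lr_profile()`), Cohen's *d* and
  Φ² effect sizes (`cohens_d()`, `phi_squared()`);
* a synthetic-cohort generator with a latent credibility state
  (`simulate_cohort()`, `recovery_report()`) so the full pipeline can be
  exercised without clinical data;
* a command line (`inst/cli/eindex`, or `run_cli()`) with `score`,
  `evaluate`, `roc`, `ranges`, `simulate`, and `fixtures` subcommands.

## Worked example

Simulate a mixed clinical/forensic-style cohort of 452 examinees (20%
non-credible planted), score it against the default EI-5 battery, and
evaluate the index against the simulated G-3 criterion:

```r
library(eindex)

battery <- ei5_battery()
cohort  <- simulate_cohort(sim_params(n = 452, seed = 2024), battery)
scored  <- score_cohort(cohort, battery)
table(scored$ei_band)
#>       Pass Borderline       Fail
#>        293         67         92

auc_mann_whitney(scored$ei_total, scored$noncredible)
#> AUC = 0.910 [0.870, 0.950]

g3   <- g3_label_cohort(scored)
keep <- g3 != "Indeterminate"   # single-failure cases are excluded
roc_sweep(scored$ei_total[keep], (g3 == "Fail")[keep], 1:7)
#>   cutoff br_fail sensitivity specificity   occ
#> 1      1   0.525       0.895       0.581 0.651
#> 2      2   0.359       0.826       0.774 0.786
#> 3      3   0.251       0.767       0.897 0.868
#> 4      4   0.199       0.709       0.947 0.894
#> 5      5   0.155       0.628       0.980 0.902
#> 6      6   0.119       0.500       0.990 0.881
#> 7      7   0.103       0.453       0.997 0.876
```

Reading the sweep: as the cutoff moves from liberal (≥1) to conservative
(≥7), the base rate of failure (`br_fail`, the fraction of the cohort
flagged) falls, sensitivity falls, and specificity rises — the standard
cutoff ≥4 is where specificity clears the ≥.90 norm while sensitivity is
still near .70 in this cohort. Band-wise base rates and likelihood ratios
against each criterion come from
`range_br_analysis(scored$ei_band, list(WMT = scored$wmt_fail, ...))`.

The same pipeline from a shell:

```sh
Rscript inst/cli/eindex simulate --n 452 --seed 2024 --out cohort.csv
Rscript inst/cli/eindex score --battery default --cohort cohort.csv --out scored.csv
Rscript inst/cli/eindex roc --cohort scored.csv --score ei_total \
    --criterion noncredible --cutoffs 1:7
```

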