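# biaffm

Validation and development of bioelectrical impedance analysis (BIA)
equations for fat-free mass (FFM), against a dual-energy X-ray
absorptiometry (DXA) reference.

Single-frequency (50 kHz) BIA estimates FFM through population-specific
regression equations, most of them built on the impedance index S²/R
(stature squared over resistance, cm²/Ω), which is proportional to the
body's conductive volume. An equation developed in one population can be
badly biased in another. This package is for researchers who need to
quantify that bias and, when necessary, develop a new equation — the
motivating case being young, lean, physically active males (military
cadets), whose specific equation is

```
FFM (kg) = 0.508·Wt + 39.234·log10(S²/R) − 48.263
```

with weight `Wt` in kg, stature `S` in cm, resistance `R` in Ω.

It provides:

- **an evaluable catalogue** of nine FFM equations (`equation_catalogue()`,
  `predict_ffm()`, `predict_specific()`) with exact published unit
  conventions;
- **the method-agreement statistics suite**: difference summary, paired
  t-test with conditional log10 transform, Lin's concordance correlation
  CCC = ρ·C_b decomposed into precision and accuracy, adjusted R² and SEE
  from the calibration regression, pure error √(Σ(ŷ−y)²/n), Bland–Altman
  95% limits of agreement with the proportional-bias trend test, and
  TEM/CV% for test–retest reliability (`build_report()`,
  `agreement_table()`, `validate_equations()`, `technical_error()`);
- **the development/cross-validation pipeline**: random 2:1 split,
  p-value stepwise regression (enter 0.05 / remove 0.10) over the fixed
  eight-predictor pool, residual normality check, and per-group agreement
  reports (`develop_and_validate()`);
- **a synthetic cohort generator** (`generate_cohort()`) emulating the
  cadet sample (n = 396, stature 175.8 ± 6.4 cm, FFM 58.2 ± 6.5 kg,
  FM 17.2 ± 3.9%) in which the specific equation is the true generating
  model, so every pipeline stage is testable without subject-level data.

## Worked example

The `analysis/` directory is a numbered workflow; each script prints its
findings and writes tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # simulate the cohort
Rscript analysis/02_validate_equations.R   # validate the catalogue vs DXA
Rscript analysis/03_develop_equation.R     # develop + cross-validate
Rscript analysis/04_reliability.R          # test-retest TEM / CV%
```

Output of steps 2 and 3 on the default seed:

```
Validated 9 equations on n = 396 subjects
  7 of 8 published equations differ significantly from DXA
  CCC range (published equations): 0.72-0.92
Population-specific FFM equation (stepwise OLS on the development group)
  FFM = 0.469*weight + 40.815*log10_impedance_index -48.358
  DG n = 264, adj R2 = 0.87, SEE = 2.2 kg, residual normality p = 0.924
  specific_dg    n=264  diff 0.0 +/- 2.2 kg  CCC 0.93  SEE 2.2  PE 2.2
  specific_cvg   n=132  diff -0.1 +/- 2.2 kg  CCC 0.94  SEE 2.2  PE 2.2
  specific_total n=396  diff -0.0 +/- 2.2 kg  CCC 0.93  SEE 2.2  PE 2.2
  CVG paired p = 0.439 (no significant bias is the target outcome)
```

Reading this: most published equations carry a significant mean bias on
this population (up to ±3 kg), while the freshly developed two-predictor
equation — stepwise selection recovered exactly weight and the log
impedance index, with coefficients near the generating truth — shows a
0.0 kg mean difference on the development group (an OLS identity), no
significant bias on the held-out cross-validation group, concordance
above 0.90, and a 2.2 kg standard error of estimate.

The same machinery works on real cohorts: load a CSV with columns
`subject_id, age, sex, weight_kg, stature_cm, resistance_ohm,
reactance_ohm, fm_kg, bmc_kg, lst_kg` via `read_cohort()`, then call
`validate_equations()` / `develop_and_validate()` directly.

```r
library(biaffm)
cohort <- generate_cohort(cohort_config(), seed = 42)
reports <- validate_equations(cohort)
agreement_table(reports, round = TRUE)[, c("equation_id", "mean_diff",
                                           "sd_diff", "ccc", "see")]
```

See `vignettes/ffm-equation-validation.Rmd` for the statistical model,
the generator's design and its known limitations.

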