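# mixref

Indirect reference intervals from mixed laboratory data by
maximum-likelihood mixture estimation.

## The problem

Clinical reference intervals are conventionally established the *direct*
way: recruit at least 120 verified-healthy reference individuals per
subgroup and take the central 95% of their values. For tests with many
subgroups — such as thyroid function in pregnancy, where
thyroid-stimulating hormone (TSH) and free thyroxine (FT4) shift markedly
by trimester — that is prohibitively expensive, and most laboratories fall
back on manufacturer intervals that fit their local population poorly.

*Indirect* methods instead start from the mixed results a laboratory
already holds — mostly non-pathologic, partly pathologic — and recover the
non-pathologic component statistically. `mixref` implements the
maximum-likelihood flavour of this idea as a reusable, fully tested
pipeline:

1. **Cleaning cascade** — raw records pass seven ordered exclusion
   criteria (missing values, missing age, non-female sex, age outside
   20–45 years, multiple records per patient, values outside the assay's
   analytical measurement range, TPO-Ab above 34 IU/ml), each exclusion
   attributed to the first criterion hit so the funnel reconciles exactly.
2. **Stratification** — by gestational trimester (weeks 4–12, 13–27, ≥28)
   and five-year maternal age bands (20–25 … 41–45).
3. **Mixture estimation** — for each stratum, a kernel density estimate
   locates the dominant mode ("main part", assumed non-pathologic); EM then
   fits a mixture

   f(x) = w_h · f_h(x | θ_h) + Σ_j w_j · f_j(x | θ_j)

   whose healthy component f_h is gamma for right-skewed analytes (TSH)
   and normal for symmetric ones (FT4), with optional low/high pathologic
   contamination components. Model structure is selected by a
   Kolmogorov–Smirnov statistic on the main part.
4. **Reference limits** — the 2.5th and 97.5th percentiles of the *fitted
   healthy component* (parametric inverse CDF), not of the raw data.
5. **Reporting** — population tables, age-band medians with
   Kruskal–Wallis tests, and abnormal-rate comparisons (χ², 1 df) against
   the built-in pregnancy-guideline intervals for Roche assays.

Because real laboratory archives cannot be redistributed, the package
ships a synthetic-cohort generator whose healthy components are calibrated
so that their true 2.5/97.5 percentiles equal published trimester-specific
limits (TSH 0.40–4.09, 0.57–4.04, 0.73–4.07 mIU/L; FT4 12.2–20.5,
10.2–18.2, 9.0–15.5 pmol/L). Every record carries a ground-truth label, so
cleaning, estimation and reporting are all testable against known truth.

## Worked example

```r
library(mixref)
cfg <- pipeline_config(truth = default_truth_params(), seed = 1,
                       out_dir = "mixref-run")
res <- run_pipeline(cfg, quiet = TRUE)
print(res$report)
```

which prints (abridged):

```
== Reference intervals (fitted vs guidelines) ==
  TSH  first   fitted 0.46-3.80  guidelines 0.09-4.52
  TSH  second  fitted 0.63-3.88  guidelines 0.45-4.32
  TSH  third   fitted 0.78-3.75  guidelines 0.30-4.98
  FT4  first   fitted 11.9-20.7  guidelines 13.2-20.8
  FT4  second  fitted 9.9-18.4   guidelines 9.8-18.9
  FT4  third   fitted 8.7-15.6   guidelines 9.0-15.2

== Abnormal rates (guidelines vs fitted), % ==
  first   TSH              4.11 vs  10.53   p = <2e-16
  first   FT4             10.40 vs   4.79   p = <2e-16
  ...
```

The simulated cohort here uses the default scaled-down sizes
(6000/4000/2000 records per trimester, 2% hypothyroid + 2% hyperthyroid +
5% TPO-Ab-positive contamination). The fitted TSH intervals come out
clearly narrower than the guideline ones while FT4 is comparable — the
characteristic signature of the indirect ML method — and the fitted limits
track the generator's true healthy percentiles (first-trimester truth
0.40–4.09 mIU/L). Estimation accuracy improves with stratum size; see the
vignette for the calibration study at n = 50 000.

Lower-level entry points: `clean_cohort()`, `stratify_cohort()`,
`estimate_density()`, `fit_analyte()` / `fit_mixture_em()`,
`reference_limits()`, `compare_abnormal_rates()`, `build_report()`. A thin
command-line wrapper lives at `inst/scripts/mixref-pipeline.R`.

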