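---
title: "Indirect reference intervals by maximum-likelihood mixtures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect reference intervals by maximum-likelihood mixtures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixref)
```

## The model

A laboratory archive of an analyte in a broad population is a mixture of a
dominant non-pathologic ("healthy") component and pathologic
contamination. `mixref` models one stratum's values as

$$ f(x) \;=\; w_h\, f_h(x \mid \theta_h) \;+\; \sum_{j} w_j\, f_j(x \mid \theta_j),
   \qquad w_h + \textstyle\sum_j w_j = 1, $$

where $f_h$ is the healthy density and the $f_j$ are optional
contamination components seeded below and/or above the healthy mode. The
healthy family is chosen by the analyte's shape: **gamma** for
right-skewed analytes such as TSH (the gamma's flexible shape captures the
skew without any normalising transformation) and **normal** for
approximately symmetric analytes such as FT4. Contamination components use
the same family as the healthy one; since only the healthy component's
central quantiles are reported, the contamination's exact parametric form
has little influence, and a uniform family keeps every M-step identical.

The reference interval is the pair of **parametric quantiles of the fitted
healthy component alone**, $F_h^{-1}(0.025)$ and $F_h^{-1}(0.975)$ at the
default 95% coverage — percentiles of the estimated non-pathologic
distribution, not empirical percentiles of (truncated) data. Parametric
tails are smoother and extrapolate sensibly where contamination overlaps.

### Fitting

1. A Gaussian kernel density estimate (bandwidth by Silverman's rule,
   grid spanning the data ± 3 bandwidths) locates the global mode, taken
   to be the centre of the healthy population.
2. The healthy component is initialised at that mode with spread
   IQR/1.349; contamination components are seeded at the 1st/99th sample
   percentiles with inflated spread. The healthy component receives an
   initial weight of 0.90 — an assumed healthy:pathologic ratio of 9:1 —
   and the rest is split evenly. The EM result is insensitive to this
   starting ratio (verified over 0.80–0.95; the test suite requires the
   final limits to move by less than 1%).
3. Standard EM: responsibilities are computed in log space with
   log-sum-exp renormalisation; M-steps are the weighted normal MLE
   (closed form) and the weighted gamma MLE, which solves
   $\log k - \psi(k) = \log \bar A - \bar L$ (weighted arithmetic-mean /
   mean-log statistics) by a Newton iteration on $k$ with derivative
   $1/k - \psi'(k)$, a guaranteed-positive bracketing fallback, score
   tolerance $10^{-10}$, and a shape cap of $10^6$ for (near-)constant
   input. Iteration stops when the relative log-likelihood change falls
   below $10^{-8}$ or at 2000 iterations. A component whose weight falls
   below $10^{-4}$ (or whose M-step degenerates) is pruned and the smaller
   mixture refitted, so the recorded log-likelihood trace is always the
   monotone trace of the final structure.

### Main-part diagnostics and model selection

The claim that the central mass of the data is non-pathologic is checked
with a Kolmogorov–Smirnov statistic restricted to the **main part**,
operationalised as the healthy component's central 90% (5th–95th
percentile; a configurable choice — the region bounds are an argument of
`ks_main_part()`). The statistic is the sup distance between the fitted
full-mixture CDF and the empirical CDF over sample points in that region.

Candidate structures (healthy alone; healthy + low, + high, + both
contamination components) are compared by this statistic under a
**smallest-adequate-model rule**: a candidate is adequate when its KS
distance falls below the canonical 95% Kolmogorov critical scale
$1.36/\sqrt{n}$, and among adequate candidates the most parsimonious wins
(ties by smaller KS, then higher log-likelihood); only when nothing is
adequate does the minimum-KS fit win. The rationale: on an uncontaminated
sample every candidate's KS lands well below the critical scale and their
differences are pure sampling noise, yet the minimum-KS fit would let
spare components absorb tail mass and bias the healthy quantiles — the
adequacy threshold stops that, while genuine contamination misfit exceeds
the scale and still forces the richer model. After fitting, the healthy
component must hold the largest weight; if EM has drifted away from that
labelling, the largest-weight component is re-identified as healthy with a
warning.

One identifiability limit is worth knowing: symmetric additive
contamination at moderate rates (e.g. ±3 pmol/L on an FT4-like normal at
5% + 5%) widens the single-component fit only slightly, and within the
central region the KS statistic cannot always distinguish it from the
healthy-only model at $n \approx 30\,000$. The selected single component
then over-states the healthy spread by a few percent (about 3–4% on the
limits in the packaged recovery tests) — still well inside the 5%
recovery tolerance the test suite enforces, but a caution against reading
the last digit of an FT4 limit.

## Cleaning cascade

Seven ordered criteria: (1) missing analyte values (or missing patient
identifier), (2) missing age, (3) sex not female, (4) age outside 20–45
years (bounds inclusive — 20 and 45 are retained), (5) more than one
record per patient across the input period (all of that patient's records
dropped; one row = one test set), (6) TSH or FT4 strictly outside the
analytical measurement range (TSH 0.005–100.00 mIU/L, FT4 0.3–100 pmol/L;
values exactly at a bound are retained), (7) TPO-Ab strictly above
34 IU/ml (exactly 34 is retained). Each excluded record is attributed to
the **first** criterion it violates, which makes the exclusion funnel
reconcile record-for-record. Records with gestational week missing or
below 4 — before the first trimester's defined start — are excluded
afterwards and logged separately, since the trimester mapping (4–12 first,
13–27 second, ≥28 third) is undefined there.

## The synthetic cohort and what it does (not) emulate

The generator defines the study conditions for every test:

* **Healthy laws per trimester** are calibrated deterministically so that
  their true 2.5/97.5 percentiles equal published trimester-specific
  limits (TSH 0.40–4.09 / 0.57–4.04 / 0.73–4.07 mIU/L; FT4 12.2–20.5 /
  10.2–18.2 / 9.0–15.5 pmol/L). A gamma has two free parameters, so the
  calibration targets the two tail limits and the median is implied: the
  first-trimester TSH law gives 1.58 mIU/L against an observed 1.59 (and
  the FT4 normal's mean 16.35 against an observed median 16.00) — a
  recorded, accepted discrepancy of the two-parameter fit.
  The gamma calibration reduces to a 1-D root find on the shape (the
  quantile ratio is monotone in it), followed by a closed-form rate.
* **Age structure** follows the five-band population profile
  22/44/23/9/2% (20–25 … 41–45), uniform within band; the healthy FT4 mean
  declines by 0.05 pmol/L per year of age around the reference age 28,
  mirroring the observed age trend. TSH is generated age-flat.
* **Contamination**: hypothyroid records multiply TSH by 4 and shift FT4
  down 3 pmol/L; hyperthyroid records multiply TSH by 0.05 and shift FT4
  up 3 pmol/L (multiplicative for the skewed analyte, additive for the
  symmetric one); TPO-Ab-positive records draw an antibody titre above the
  cutoff and carry TSH shifted up ×1.5. Default rates are 2% + 2% + 5%.
  The pathologic forms are conventions — plausible, clearly displaced but
  overlapping — not claims about real disease distributions.
* **Dirty records** plant each cleaning trigger disjointly (one violated
  criterion per record) at configurable rates (defaults 0.2–1%), so
  per-criterion exclusion counts can be checked exactly.
* A single seed drives everything through deterministic per-trimester
  substreams; regeneration is bit-identical.

Not emulated: assay measurement error, batch/calendar drift, iodine
status, correlated TSH–FT4 physiology within subject, gestational-week
continuity within a trimester, and repeat-testing dynamics. Passing the
packaged tests therefore shows the estimator recovers a *known mixture of
the assumed families* under realistic contamination — it does not certify
performance on any specific real archive, where family misfit and
unmodelled heterogeneity enter.

## Problem sizes and numerical choices

The calibration study fits n = 50 000 uncontaminated draws (coverage
inside the estimated interval lands within three Monte-Carlo standard
errors of 95%); recovery tests use n = 30 000 with 10% contamination and
require healthy-limit recovery within 5% relative error; the default
simulated cohort is 6000/4000/2000 per trimester. These sizes keep the
whole suite in a few minutes on one core while leaving Monte-Carlo error
far below the tolerances tested.

Other fixed choices: EM tolerance $10^{-8}$ (relative log-likelihood),
max 2000 iterations; component-collapse threshold $10^{-4}$; gamma-MLE
score tolerance $10^{-10}$, shape cap $10^6$; density grid 512 points;
abnormal-rate χ² without continuity correction (with a Fisher fallback
when an expected cell drops below 1, and a paired McNemar variant behind a
flag, since classifying the same subjects under two interval sets is
paired data); display rounding TSH 2 decimals / FT4 1 decimal with all
comparisons computed pre-rounding; out-of-interval strictly outside, a
value exactly at a limit is normal.

## Known limitations

* Trimester-level stratification ignores within-trimester gestational-week
  heterogeneity; continuous (week-resolved) reference curves are the
  natural extension and out of scope here.
* The FT4 symmetric-contamination identifiability limit above.
* Small strata (≲ 2000 records) give visibly noisy limits; the pipeline
  fits any stratum with ≥ 30 values but the uncertainty is the user's to
  judge.
* The cleaning cascade keys deduplication on the patient identifier over
  the whole input period; records lacking an identifier are excluded as
  missing values, and cross-pregnancy linkage is not attempted.
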