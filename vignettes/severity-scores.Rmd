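---
title: "Severity scores and mortality-prediction evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity scores and mortality-prediction evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscores)
```

## The problem

Adult splenic abscess is a rare intra-abdominal infection whose mortality
remains near 14%. The clinical question the package serves is risk
stratification at the emergency department (ED) door: given one set of
triage vitals, basic labs and history flags, how well do four rapid
physiologic scores — RAPS, REMS, MEWS and MEDS — predict in-hospital death,
and at what cutoff should each be read? The package implements the scores,
a synthetic cohort generator calibrated to the published survivor and
non-survivor margins of a 114-patient reference cohort, and every statistic
in the evaluation chain.

## The score calculators

Each score is a sum of banded point contributions. The band tables are
transcribed as exhaustive threshold chains, so every finite input falls in
exactly one band; property tests sweep the full physiological ranges at 0.1
resolution to confirm single-band coverage, the unimodal "valley" shape of
points around each zero band, and the attainable extremes (RAPS 0–16,
REMS 0–26, MEWS 0–14, MEDS 0–27).

Conventions that the published tables leave open are fixed as follows, as
package policy:

- **Rounding.** Real-valued vitals are rounded half-up to the integer grid
  of the band tables (temperature to 0.1 °C) before lookup. Published
  medians are reported at 0.5 resolution (e.g. a pulse rate of 120.5), so a
  deterministic tie rule is needed; half-up is the one clinicians apply by
  hand. Thus 120.5/min falls in the 110–139 band and 38.45 °C reads as
  38.5 °C (+2 MEWS points).
- **One-unit table gaps.** The MEWS table jumps from "<70" (+3) to "71–80"
  (+2) for systolic BP, and from "<40" (+2) to "41–50" (+1) for heart rate.
  A systolic pressure of exactly 70 or a heart rate of exactly 40 is
  assigned the adjacent *higher-acuity* band: conservative triage should
  never under-score a boundary value. Both boundaries are covered by tests.
- **Missing temperature band.** The MEWS temperature row has no +1 or +3
  entries; the absent bands are treated as genuinely non-existent, not as
  omissions to repair.
- **AVPU from GCS.** When a chart records GCS but not AVPU, the
  conventional correspondence (14–15 Alert, 9–13 Voice, 4–8 Pain, 3
  Unresponsive) is applied; an explicit AVPU always wins.
- **MEDS flags.** Septic shock and altered mental status are consumed as
  chart-abstracted booleans — the package does not re-derive septic shock
  from hemodynamics, because its clinical definition is consensus-based
  rather than a threshold rule. When the altered-mental-status flag is
  absent it defaults to GCS ≤ 13. The tachypnea-or-hypoxia criterion is
  strict, as printed: RR > 20, or oxygen by mask, or SpO₂ < 90; RR = 20
  and SpO₂ = 90 do not qualify.
- **Missing inputs.** The default is an explicit error naming the missing
  field. An opt-in `impute = TRUE` mode substitutes the zero-band normal
  value, messages each substitution, and records it on the returned
  breakdown — never silently.

## The synthetic cohort generator

The reference cohort's per-patient data are unpublished; its tables report
each arm only as medians with IQRs (continuous variables) and counts
(categorical ones). The generator therefore works per arm:

- **Continuous variables** (age, pulse rate, respiratory rate, MAP,
  temperature, platelets, leukocytes) are modelled log-normally: positive
  support and mild right skew are typical of vitals and labs. The median
  fixes the log-location exactly (`mu = log(median)`), and the log-scale SD
  is the least-squares fit of the quartiles,
  `sigma = log(q3/q1) / (2 z0.75)` — exact with zero residual whenever the
  reported IQR is log-symmetric about the median. Sampling uses the inverse
  CDF restricted to the 1st–99th percentile (probability-symmetric, so the
  median is untouched) followed by a hard physiological clamp.
- **Categorical variables** (GCS band, sex, septic shock, terminal illness,
  etiology, abscess multiplicity, treatment) follow the published arm
  frequencies; a sampled GCS band is filled with a uniform integer within
  the band, AVPU is derived from it, and the altered-mental-status flag is
  GCS ≤ 13.
- **Unpublished inputs.** SpO₂ and systolic BP are absent from the
  reference tables but required by REMS/MEWS/MEDS. Defaults: SpO₂ is a
  clipped normal — mean 97 (SD 2) in survivors, 93 (SD 4) in non-survivors,
  reflecting ordinary ED oximetry with mild desaturation in sicker
  patients — and systolic BP is derived from MAP assuming a 40 mmHg pulse
  pressure (SBP = MAP + 2/3·40). The remaining MEDS flags (nursing-home
  residence, lower respiratory infection, bands > 5%, oxygen by mask) get
  probabilities 0.05/0.10/0.15/0.05 in survivors, doubled in non-survivors.
  All of these are explicitly synthetic, spec-overridable knobs, never
  published quantities.

Two calibration details are deliberate choices. The non-survivor
septic-shock frequency is taken as the count-based 6/14 ≈ 0.4286 rather
than the printed 42.84%, which appears to round the same count differently.
And the survivor respiratory-rate row prints a degenerate IQR (median 20,
IQR 19–20, upper quartile equal to the median), which a strictly monotone
quantile fit cannot accept; the upper-quartile target is widened to 20.5 —
half the printed reporting resolution — while the median target stays 20.

What the generator does *not* emulate: correlation between variables within
a patient (the published tables carry none, so variables are independent
within an arm), longitudinal trajectories, measurement rounding patterns of
real charts, and any association between the score inputs beyond the
arm-level shift. Consequently, passing calibration tests shows the
generator hits the published *margins*; it does not certify that score
performance on these cohorts matches performance on real patients — with
independent inputs, score AUROCs on synthetic cohorts tend to sit below a
real cohort's values, where deranged vitals co-occur. The pipeline tests
therefore check direction (every score discriminates, predicted death
probabilities are higher in non-survivors) rather than the published AUROC
magnitudes.

## The evaluation statistics

- **Mann–Whitney U** uses midranks for ties. The exact two-sided p-value
  comes from the full permutation distribution of the rank sum, computed by
  dynamic programming over doubled midranks (integers even under ties), as
  `min(1, 2·min(P(U ≤ u), P(U ≥ u)))`; tests verify it against independent
  brute-force enumeration over all group assignments. Exact mode is used
  automatically when `choose(nx+ny, nx) ≤ 1e6`; beyond that the
  tie-corrected normal approximation with 0.5 continuity correction takes
  over (requesting exact mode on an infeasibly large tied problem falls
  back with a recorded note).
- **Fisher's exact test** conditions on both margins and sums the
  probabilities of all tables no more probable than the observed one — the
  standard two-sided definition (the doubling alternative exists; this
  package does not use it). 2×2 tables use the vectorised hypergeometric
  support; r×2 tables are enumerated when the search space is ≤ 5·10⁴
  vectors and otherwise estimated by conditional Monte Carlo over
  margin-preserving tables with a fixed internal seed (2·10⁴ draws), so
  results stay reproducible and the caller's RNG stream is untouched.
- **Logistic calibration** fits `p = 1/(1 + exp(−(β₀ + β₁X₁)))` by IRLS,
  initialised at `(logit(base rate), 0)`, tolerance 1e-8 on the gradient
  max-norm, at most 50 iterations. Complete separation is detected up front
  and reported as an error naming the direction; a singular weight matrix
  is an explicit error. Standard errors come from the inverse observed
  information. Tests verify agreement with `glm(..., binomial)` to 1e-6
  and slope recovery with < 5% bias at n = 5000 over 200 replicates for
  true slopes 0.25 and 0.5.
- **ROC analysis** thresholds at every distinct score (ties grouped),
  positive iff score ≥ threshold, AUC by trapezoid — algebraically equal to
  the normalised Mann–Whitney U with ties counted half, which the tests
  assert on 1000 random tied samples. The published analyses name an
  "optimal cutoff" without stating the rule; this package uses Youden's
  J = sensitivity + specificity − 1, the default in ROC practice, with ties
  broken toward higher specificity and then toward the higher threshold.
  That choice reproduces consistent confusion-matrix arithmetic with the
  published test characteristics, but it remains a package decision, not a
  reported fact.
- **Test characteristics** are always derived from integer confusion
  counts, so accuracy, PPV and NPV are exact ratios; reconstructing the
  counts implied by the published composition (14 non-survivors, 100
  survivors) and the published sensitivity/specificity reproduces every
  published accuracy/PPV/NPV cell to two decimals.

The pipeline's probability-of-death stage reports both mean (SD) and median
(IQR) of the per-patient predicted probabilities in each arm: published
summaries of this quantity are labelled as means but formatted like
quantiles, so both are given.

## Problem sizes and runtime choices

Test and script problem sizes are chosen so the whole suite runs in well
under a minute: calibration checks use 10⁴ patients per arm (median
recovery within 3%, categorical frequencies within exact binomial 95%
bands), logistic recovery uses 200 replicates of n = 5000, the
AUROC/U-statistic equivalence uses 1000 small random samples, and exact-test
cross-validation enumerates all 2×2 tables with ≤ 12 observations plus
random tied rank problems of the same size. The default cohort size for
worked examples is the reference composition, 100 + 14.

## Known limitations

- Independence of inputs within an arm (above) is the biggest gap between
  synthetic and real cohorts; published AUROC magnitudes for the reference
  cohort are out of reach of any generator fitted only to margins, and are
  deliberately not asserted.
- The scores are implemented for adults (age ≥ 18); pediatric bands are out
  of scope, as are APACHE II and qSOFA.
- Exact Mann–Whitney enumeration is refused (with a logged fallback) for
  tied problems beyond 10⁶ combinations rather than approximated silently.
- The Youden cutoff rule and the half-up rounding convention are package
  policies where the source tables are silent; both are centralised and
  tested so alternative conventions could be swapped in.
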