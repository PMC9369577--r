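---
title: "Dynamic liver-enzyme trends as predictors of bile-duct stones: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic liver-enzyme trends as predictors of bile-duct stones: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdltrend)
```

## The clinical question and the analysis it implies

In-patients with suspected choledocholithiasis (CDL) accumulate serial
liver panels while they wait for ERCP or EUS. The analysis this package
implements asks whether the *direction and magnitude of change* in total
bilirubin, ALT, and ALP across the 72 hours before the procedure predicts
what the endoscopist will find: a rising pattern suggesting a retained,
obstructing stone, a falling pattern suggesting a stone that has already
passed. Both orientations matter clinically — an *increase* is evaluated
as a test for the *presence* of stones, a *decrease* as a test for their
*absence* — and the package keeps the two orientations explicit throughout
(`target = "presence"` / `"absence"` in `build_confusion()`).

## Trend definition

For one analyte, let $v_1, \dots, v_n$ be the measurements with
$-72 \le t \le 0$ hours (day-of-procedure draws included). The features
are

$$\text{max rise} = \max\Big(0,\ \max_{i<j} \frac{v_j - v_i}{v_i}\Big),
\qquad
\text{max fall} = \max\Big(0,\ \max_{i<j} \frac{v_i - v_j}{v_i}\Big),$$

computed over *all* time-ordered pairs with the earlier value as
denominator. Design choices worth stating:

- **Pairwise, not anchored.** Nothing pins the change to the admission or
  day-of-procedure value; any excursion inside the window — within 48, 24,
  or 12 h — is captured. Whether the original clinical usage anchored on
  the final pre-procedure value is not determinable from the published
  description, so the anchor is a config switch
  (`trend_config(anchor_mode = "last_value")`) and the pairwise scan is
  the default: it dominates the anchored value and degrades gracefully
  when the last draw is missing.
- **Rise and fall are computed independently**, so a non-monotone
  ("ball-valve") series can flag both; neither definition subtracts the
  other.
- **Zero denominators are skipped.** A pair with $v_i = 0$ contributes no
  relative change; if no usable pair remains the feature is undefined
  rather than infinite.
- **Undefined propagates by three-valued logic.** A patient needs at
  least two usable in-window values per analyte. Combined predictors
  (bilirubin AND/OR ALT, any-of-three) treat an undefined operand as
  unknown: AND is unknown whenever any operand is unknown (even if
  another is false — the patient simply cannot be evaluated for the
  combination), OR is true as soon as a defined operand is true. Patients
  with unknown flags are dropped listwise per predictor, which is what
  makes the modelled $n$ differ across predictor rows, exactly as
  per-model denominators differ in retrospective cohorts with patchy
  panels.
- **Units.** Bilirubin is compared in µmol/L internally
  (1 mg/dL = 17.1 µmol/L); mixed-unit series are converted before any
  ratio is formed, and classification is invariant to the reporting unit.

Thresholds default to 30% and 50%: the smaller replicates earlier work on
relative enzyme changes, the larger demands enough signal to clear
laboratory measurement variation. Monotonicity (a 50% flag implies the
30% flag) is enforced by construction and tested as a property.

## Guideline engines

The three criteria sets are encoded directly:

| | high | intermediate |
|---|---|---|
| ASGE 2010 | stone on US; cholangitis; bilirubin > 4 mg/dL; bilirubin 1.8–4 mg/dL **and** CBD > 6 mm | bilirubin 1.8–4 mg/dL; CBD > 6 mm; abnormal non-bilirubin tests; gallstone pancreatitis; age > 55 |
| ASGE 2019 | stone on US **or cross-sectional imaging**; cholangitis; bilirubin > 4 mg/dL **and** CBD > 6 mm | bilirubin ≥ 1.8 mg/dL; CBD > 6 mm; abnormal non-bilirubin tests; gallstone pancreatitis; age > 55 |
| ESGE 2019 | cholangitis; stone on US | any abnormal liver test; CBD > 6 mm |

"Low" is the absence of every criterion. Conventions: "abnormal" is a
strict comparison against the upper limit of normal; the 1.8–4 band is
closed on both ends; the bilirubin used is the measurement closest in time
before the procedure; missing imaging or flags count as
criterion-not-met (bedside behaviour — an unavailable finding cannot
trigger a criterion — and it keeps every patient classifiable). The
aggregate "abnormal liver tests" flags OR over the *measured* analytes and
are unknown only when nothing relevant was measured. Reference ranges are
laboratory-specific and therefore configurable (`reference_ranges()`,
optionally from YAML); the defaults (TBILI 21 µmol/L, ALT/AST 40 U/L,
ALP 130 U/L, GGT 60 U/L) are typical adult limits. Only total bilirubin
enters the criteria; direct bilirubin is carried in the data model but
unused, since none of the criteria sets reference it.

## Performance metrics

Every index test is summarised by accuracy, sensitivity, specificity,
PPV, and NPV on its own 2×2 table, each with a 95% binomial CI on the
metric's own denominator. Two interval families are defaults in different
places: Clopper–Pearson (exact beta quantiles) for the trend-predictor
tables, whose small denominators and frequent 0/``n`` cells need exact
endpoints (a lower bound of exactly 0, an upper bound of exactly 100%),
and Wald for the large guideline-category rows. Wilson is available
throughout. A zero denominator (for instance PPV with no positive calls)
yields "not reportable" rather than NaN. Reported percentages are rounded
to one decimal half-away-from-zero; all computation is at full precision.

A note on conventions: when a *decrease* is evaluated against the
*absence* of stones, "condition-positive" means *no stone found*, so the
specificity column reads "fraction of stone-positive patients without the
flag". The duality is exact — re-orienting the complementary flag to the
complementary condition swaps sensitivity with specificity and PPV with
NPV — and is pinned by a property test.

## The synthetic cohort generator

Because the registry data behind the analysis are not shareable, the
generator produces cohorts with the structure the method assumes, and its
defaults are the published cohort's marginals, fixed once:

- **Latent states.** Each patient is `retained` (stone at endoscopy;
  probability = prevalence 0.708), else `passed` (30% of negatives) or
  `never`. `cdl_found` is true exactly for `retained`.
- **Baselines.** Per-analyte log-normal, moment-matched to the published
  group means/SDs (e.g. total bilirubin 64.9 (62.1) µmol/L in positives,
  60.6 (63.3) in negatives); enzyme distributions are right-skewed with
  SD of the order of the mean, which a log-normal reproduces while a
  normal would go negative. AST and GGT have no published moments and
  their defaults are uncalibrated round numbers, flagged as such.
- **Trajectories.** Retained: baseline × 1.15 per day from the window
  start — a mild obstructive rise. Passed: baseline × 0.55 per day after
  a passage time drawn uniformly over the window (uniform being the
  minimal assumption for an unobserved event; both rates are parameters).
  The decay default means enzymes roughly halve daily after
  decompression, consistent with the short plasma half-lives that make
  falling enzymes a plausible passage signal. Never: flat. All values are
  multiplied by log-normal noise with unit mean and CV 0.15 (typical
  short-term biological plus analytical variation for these analytes).
- **Missingness.** Lab draws exist at −72/−48/−24/0 h with probabilities
  195/878, 358/878, 565/878, 538/878 — the published per-offset
  availability — drawn once per patient-offset and shared across
  analytes, since liver enzymes are ordered as a grouped panel.
- **Imaging and demographics.** Stone seen on US with probability 0.547
  given a retained stone and *never* otherwise; CBD > 6 mm with
  probability 0.553 (positives) / 0.479 (negatives), sizes for dilated
  ducts from truncated normals 12.4 (4.5) / 11.6 (3.8) mm; age from
  truncated normals 59.3 (21.2) / 66.0 (18.2); 58.6% female; ERCP versus
  EUS at 97.7% / 86.0% by group.

What the generator deliberately does **not** emulate: informative
re-testing (the care-process bias where clinicians order repeat panels on
the patients they worry about), correlated missingness across offsets,
era/operator effects, or any dependence of passage time on enzyme levels.
Consequently the synthetic cohort separates the outcome groups more
cleanly than a real registry would — the simulated decrease predictors
reach specificities near 100% with much higher sensitivity than any real
cohort shows — so passing tests demonstrate that the *pipeline computes
the right quantities under a known mechanism*, not that the clinical
effect size is as large as simulated.

## Eligibility flow

Exclusion rules run in a declared order (adult → in-patient → indication →
prior cholecystectomy → prior sphincterotomy → stent → procedural success
→ no repeat within 14 days → minimum data), and each excluded patient is
attributed to the *first* rule that removes them, so the tally partitions
the exclusions and conservation ($|$eligible$| + \sum$ tally $= n$) holds
for any order. The published flow reports only aggregate exclusions, so
the attribution order is a package convention, configurable by passing a
different rule vector. Minimum data completeness at the cohort level means
a known procedure outcome and at least one recorded lab; the stricter
"≥ 2 usable values per analyte" requirement is enforced *per predictor*
via undefined flags, not by cohort exclusion — that is what reproduces
per-row model denominators.

## Numerical and reporting choices

- Window boundaries are closed: $t \in [-72, 0]$.
- Tie-break for extreme-achieving pairs: earliest pair in time order.
- Per-patient signed change for the density export is whichever of
  (max rise, −max fall) has larger magnitude, ties to the rise.
- Kernel densities (Gaussian, `stats::density` bandwidth defaults) are
  computed per outcome group on a common grid and renormalised so the
  trapezoid-rule integral is exactly 1 (the raw kernel estimate leaks a
  little mass beyond any finite grid).
- The generator consumes a single seeded RNG stream in patient-id order,
  so cohorts are bitwise reproducible regardless of how downstream code
  is parallelised.
- Problem sizes in the test suite: property loops use 100–1000 random
  cases; parameter-recovery runs use cohorts of 6 000–10 000 patients,
  where the binomial Monte-Carlo error (3 standard errors ≈ 1.4
  percentage points on the prevalence) is small enough to resolve the
  recovery claims; interval-coverage checks use 20 000 simulated
  binomials per true proportion so the ~0.15% simulation error cannot
  blur the exact interval's over-coverage margin.

## Known limitations

- One published inconsistency is inherited rather than resolved: the
  source cohort is described as 878 patients in the text but its
  characteristics table sums to 879 (622 + 257). The package computes
  whatever its inputs produce; reconstructions of table marginals use the
  622/257 split.
- The published guideline-performance table's "specificity" column is
  consistent with $FP/(FP+TN)$ rather than $TN/(TN+FP)$ (its CIs match
  one minus the printed value). `cdltrend` computes conventional
  specificity and does not reproduce the apparent misprint; its
  ESGE-intermediate row is likewise internally inconsistent in the source
  and is not used as a reference point anywhere.
- Category assignment treats missing findings as criterion-not-met. Where
  ascertainment differs systematically between sites, that convention can
  shift intermediate/low boundaries.
- The trend features are relative changes only; absolute-change criteria
  from earlier literature and alternating ("ball-valve") pattern
  statistics are out of scope.
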