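---
title: "Methods: swim respirometry bioenergetics and PFAS distribution metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swim respirometry bioenergetics and PFAS distribution metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfascope)
```

## The measurement model

Intermittent-flow swim respirometry alternates a flush phase (chamber
reopened to aerated water), a short wait, and a closed measurement phase
during which dissolved oxygen falls as the fish respires. Within each
closed phase the oxygen decline is, to good approximation, linear over the
10-minute window, so the per-step respiration signal is the OLS slope of
O₂ (mg/L) on time (h). `extract_slopes()` stores the *decline rate* as the
negated slope — positive when oxygen falls — and flags a step valid only
when the regression R² exceeds `r2_min` (default 0.85, strict inequality,
the conventional respirometry screen). A segment with zero variance in O₂
carries no information; it is assigned R² = 0 and marked invalid rather
than raising an error, so batch processing is robust to probe dropouts.

Microbial (background) respiration is measured in the empty chamber for
about 20 minutes before and after each trial; the correction applied is
the arithmetic mean of the two decline rates. A single-measurement
fallback exists but must be requested explicitly
(`allow_single_background`), because silently halving the information
changes the error budget.

The mass-specific unscaled rate is

$$\mathrm{MO_2^{unscaled}} = \left[\frac{\Delta[\mathrm{O_2}]}{\Delta t}
  - \left(\frac{\Delta[\mathrm{O_2}]}{\Delta t}\right)_{bact}\right]
  \times \frac{V_{resp}}{m},$$

with $V_{resp}$ the chamber volume (default 1.5 L) minus the fish volume.
No direct fish-volume measurement is available in typical trial logs, so
volume is inferred as mass divided by an assumed density of 1.0 g/mL —
fish near neutral buoyancy displace roughly their mass in water. The
density is configurable; for a 3 g fish in a 1.5 L chamber the choice
moves $V_{resp}$ by well under 1 %.

Because metabolic rate scales allometrically with body mass, rates are
standardized to a reference mass $m_{corr}$ = 0.1 kg using
$\mathrm{MO_2} = \mathrm{MO_2^{unscaled}} \times (m/m_{corr})^{1-A}$ with
$A = 0.68$, a value appropriate for cyprinodontids. The scale factor is 1
exactly at $m = m_{corr}$ and increasing in $m$ for $A < 1$; both
properties are tested.

## The trait model

The core fitted object is the exponential rate–speed curve
$\mathrm{MO_2}(U) = a\,e^{bU}$. We estimate it by OLS on the log scale
(`fit_mo2()`), i.e. a multiplicative error model. This choice is
deliberate: per-step MO₂ errors grow with the rate (slope noise is
proportional to signal), trials yield only 5–10 points so heavy machinery
is unwarranted, and the log-linear estimator is closed-form and
reproducible. A nonlinear least-squares mode (`method = "nls"`) is kept
for sensitivity checks; on an exactly exponential dataset the refinement
step is skipped because a zero-residual optimum gives `nls` nothing to
iterate on.

* **SMR** is the predicted rate at zero swimming speed, $a$.
* **MMR** is the maximum observed standardized rate across valid steps
  (ties resolved to the first step). Since the allometric factor is a
  per-fish constant, the arg-max is invariant to scaling.
* **AS = MMR − SMR** identically; a negative scope is returned with a
  warning (it indicates a failed extrapolation), never silently clipped.
* **U_crit** = $U_t + (t_1/t)U_1$ with $t$ = 14 min and $U_1$ = 0.3 BL/s by
  default. Fatigue is behavioural; $U_t$ and $t_1$ are inputs from the
  trial log, not inferred from the trace.

All valid measured steps enter the SMR fit, including the 0.7 BL/s
habituation speed — no exclusion rule is applied because none is
warranted by the protocol. A trial needs at least three valid steps with
two distinct speeds (an exponential has two parameters); fewer raises an
insufficient-data error. The threshold is configurable
(`min_valid_steps`).

## Tissue-residue metrics

Concentrations below the method reporting limit (tissue MRLs: 0.35 ng/g
PFOS, 0.49 ng/g PFOA; water: 2.3 and 1.8 ng/L) are censored to zero before
analysis; no MRL/2 substitution is applied, and background concentrations
in nonexposed fish are retained as reported. Censoring is idempotent and
keeps boundary values (conc = MRL stays).

ΣPFAS is the plain sum PFOS + PFOA; the PFOS fraction is
100·PFOS/ΣPFAS, undefined (returned `NA`, not 0) when the sum is zero.
Percent shares are computed over exactly the four core tissues (blood,
liver, muscle, ovary) of the same fish and must sum to 100; a fish
missing any of the four is excluded from the share metric and logged.
Organ:blood ratios are undefined when blood is zero (excluded, logged).
Fold changes between group ranges are reproduced range-wise —
exposed-low/control-high to exposed-high/control-low — with half-up
integer rounding for reporting. Range-wise quotients cannot reproduce
every within-study pairing (day-14 egg folds require per-group pairings
that the summary ranges do not determine), so only the range-consistent
folds are recomputed.

## The inferential layer

The concentration–trait models are
`trait ~ log(conc) * temperature (+ 1|aquarium)`. Temperature defaults to
a categorical factor (nonlinear thermal patterns); a continuous coding is
available. Log-transforming censored concentrations needs a convention
for zeros: we use log(x + c) with c equal to half the smallest tissue MRL
(0.175 ng/g), applied only when zeros are present and recorded in the
fit's provenance. The interaction is tested with a Type III Wald test
(`car::Anova`); per-temperature simple slopes (slope, SE, p, R²) are
attached only when the interaction is significant at 0.05, mirroring the
convention of drawing within-temperature regression lines only under a
significant interaction. With a single observed grouping level the mixed
model degenerates; the fit falls back to OLS and says so in its notes
(the two agree exactly in that case, which is tested). On an exactly
deterministic dataset the Wald test saturates (zero residual variance);
the interaction p is then reported as 0 with a provenance note rather
than failing a batch.

Model selection is AIC-guided with BIC and the likelihood ratio reported;
when the AIC-best model contains sex terms and a candidate identical but
for those terms exists, the simpler model is retained unless the LRT is
significant — the drop-sex convention for clarity of interpretation. The
two-sample contract chooses Welch's t or the Wilcoxon rank-sum test by a
Shapiro–Wilk check (α = 0.05) in either sample; constant samples count as
non-normal, and the Wilcoxon variant uses the normal approximation
without continuity correction so that identical samples give p = 1.

## What the generators emulate — and what they do not

`simulate_trial()` is the exact inverse of the measurement model: a
programmed SMR and exponential coefficient define per-step rates, which
are converted back into oxygen decline slopes (plus background) and
sampled at 1 Hz with additive Gaussian reading noise. Simplifications:
flush is an instantaneous reset to the 8.0 mg/L saturation baseline
(real flushes re-approach saturation asymptotically); the closed-phase
decline is exactly linear (real traces curve slightly as O₂ falls); and
the aborted fatigue step emits no measurement samples, so the ground-truth
MMR is the programmed rate at the last completed step. The fatigue time
is constructed so the U_crit formula recovers the programmed value
exactly in the noise-free case. Defaults mirror the study conditions for
adult sheepshead minnows: SMR 105 mg O₂ kg⁻¹ h⁻¹, b = 0.6 (MMR ≈ 563 at
2.8 BL/s), U_crit 2.95 BL/s, 3.26 g fish, background 0.05 mg O₂ L⁻¹ h⁻¹,
2 mg/L-scale (0.002) reading noise.

`simulate_cohort()` draws lognormal tissue concentrations with an
aquarium-level random intercept on the log scale and compound-specific
temperature multipliers at the warm level (PFOA: ovary 4.3×, liver 4.0×,
blood 2.4×, muscle 2.0×; PFOS flat — the compound-specific pattern under
warming). Exposed-group medians (PFOS: blood 5000, liver 2500, ovary
1400, muscle 500 ng/g; PFOA: 60/25/20/10) were chosen so that PFOS makes
up 94–99 % of ΣPFAS in every tissue at both temperatures and blood
carries the largest share; nonexposed medians are 40-fold lower, placing
nonexposed ovarian ΣPFAS in the tens of ng/g. Individual GSD 1.5 and
aquarium GSD 1.15 are typical magnitudes for tissue-residue variation in
replicated tank designs. The generator does not emulate uptake kinetics,
time courses, or compound competition — it produces end-of-exposure
snapshots only, so passing tests demonstrate correctness of the metric
arithmetic and the statistical machinery, not toxicokinetic realism.

`simulate_eggs()` draws independent Poisson counts with mean
n_females·(rate + trend·day); it does not model spawning autocorrelation
or clutch structure, so egg-slope inferences on real data will be
anticonservative relative to the simulated ideal.

## Numerical choices and degenerate inputs

* OLS everywhere is `stats::lm`; the independent test oracle is a
  normal-equations implementation, agreement required to 1e-9.
* R² is computed directly from residual and total sums of squares to
  avoid spurious perfect-fit warnings on noiseless fixtures; a
  zero-variance response gives R² := 0 for slope screening and `NA` for
  the trait fit.
* Half-up rounding (`floor(x + 0.5)`) is used for reported integer
  percentages and folds; base R's round-half-to-even would turn 12.5 %
  into 12.
* Fatigue-step arithmetic clamps $t_1$ into $[0, t]$ and promotes an
  on-grid U_crit to a completed step, avoiding ±2e-16 excursions outside
  the valid range.
* Seeds: every stochastic generator takes an explicit integer seed;
  noise-free paths make no RNG calls, so their outputs are byte-identical
  regardless of seed.

## Problem sizes used in validation

The validation suite uses: noise-free round-trips over a grid of
critical speeds; 200 seeded noisy trait recoveries (multiplicative
σ = 0.02, median SMR error ≈ 1.4 %, median MMR error ≈ 1.3 %); 500 null
simulations for the interaction test's type-I error (n = 20 per
temperature level, three levels); cohorts of 36 fish for metric checks
and 1000 fish for moment/multiplier recovery. These sizes give
Monte-Carlo error comfortably below the tolerances being checked while
keeping the whole suite under a minute of compute.

## Known limitations

* The slope screen, background correction and allometric standardization
  assume a well-mixed chamber and a mass-stable fish; probe drift
  correction is out of scope.
* SMR here is an extrapolation of the swim-speed curve to U = 0, not a
  quantile-based resting estimate; the two differ systematically in
  species with spontaneous activity.
* The mixed-model layer implements an intercept-only random effect for
  aquarium; richer structures (random slopes) are not provided.
* Fold-change ranges are a reporting convention, not an estimator with a
  standard error; treat them as descriptive.
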