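# pfascope

Whole-organism bioenergetics and PFAS tissue-distribution analysis for
small-bodied fish.

`pfascope` is aimed at ecotoxicologists and ecophysiologists who run
intermittent-flow swim respirometry (critical swimming speed, *U*crit,
protocols) on fish chronically exposed to perfluoroalkyl substances, and who
need to connect internal PFOS/PFOA concentrations to metabolic performance
across temperatures. It covers the full analysis chain:

1. **Respirometry** — raw dissolved-oxygen traces (flush/wait/measure
   cycles) are turned into per-step oxygen decline slopes by ordinary least
   squares, screened for validity (R² > 0.85), corrected for microbial
   background respiration (mean of pre- and post-trial empty-chamber
   measurements), converted to mass-specific oxygen consumption

   MO₂ᵘⁿˢᶜᵃˡᵉᵈ = [(Δ[O₂]/Δt) − (Δ[O₂]/Δt)_bact] × V_resp / m

   and standardized to a 0.1 kg reference mass with an allometric exponent
   of A = 0.68: MO₂ = MO₂ᵘⁿˢᶜᵃˡᵉᵈ × (m / m_corr)^(1−A).
2. **Metabolic traits** — the core model is the exponential rate–speed
   curve MO₂(U) = a·e^{bU}, fitted on the log scale (`fit_mo2()`, a classed
   S3 fit with `print`/`summary`/`coef`/`predict`/`plot`/`residuals`/
   `simulate` methods). Its intercept is the standard metabolic rate (SMR);
   the maximum observed MO₂ is the maximum metabolic rate (MMR); aerobic
   scope is AS = MMR − SMR; and the critical swimming speed is
   U_crit = U_t + (t₁/t)·U₁.
3. **Toxicokinetics** — left-censoring at method reporting limits (values
   below the MRL set to zero), ΣPFAS, PFOS fraction of ΣPFAS, tissue
   percent shares over blood/liver/muscle/ovary, organ:blood partitioning
   ratios, and range-wise fold changes.
4. **Endpoints** — hepatosomatic and gonadosomatic indices
   (100 × organ/body weight), daily and cumulative per-female egg
   production with their time slopes, and mortality rates.
5. **Statistics** — concentration-by-temperature linear (mixed) models
   with Type III Wald interaction tests, per-temperature simple slopes
   (reported only under a significant interaction), AIC/BIC/LRT-guided
   model selection with a drop-sex rule, and distribution-guided
   two-sample tests.
6. **Synthetic data** — seeded generators for every input family
   (oxygen traces, tissue-residue cohorts, egg counts) with known ground
   truth, so the full pipeline is testable without any instrument data.

## Worked example

Simulate one trial with known truth (SMR 105 mg O₂ kg⁻¹ h⁻¹, b = 0.6,
U_crit = 2.95 BL s⁻¹, 2 mg/L-scale oxygen noise), process it, and fit the
traits:

```r
library(pfascope)
cfg <- respirometry_config()
sim <- simulate_trial(trial_truth(noise_sd = 0.002), cfg, seed = 42, trial_id = "F001")
rec <- process_trial(sim$trace, sim$truth$mass, cfg)
head(rec[, c("step_index", "speed", "decline_rate", "r2", "valid", "scaled_mo2")], 4)
#>   step_index speed decline_rate        r2 valid scaled_mo2
#> 1          0   0.7     1.091739 0.9985444  TRUE   159.9129
#> 2          1   1.0     1.298552 0.9989487  TRUE   191.6624
#> 3          2   1.3     1.540591 0.9992414  TRUE   228.8197
#> 4          3   1.6     1.831638 0.9994663  TRUE   273.5006

fit_mo2(scaled_mo2 ~ speed, rec)
#> Exponential MO2-speed fit: MO2(U) = a * exp(b * U)
#>        a        b
#> 105.1000   0.5995
#> SMR (MO2 at U = 0): 105.1 mg O2 kg^-1 h^-1; n = 8 steps; R^2(log) = 1

metabolic_traits(rec, sim$ucrit_inputs, "F001", cfg)
#>   fish_id    smr    mmr     as ucrit  fit_a  fit_b  fit_r2 n_valid_steps flags
#> 1    F001 105.06 563.27 458.21  2.95 105.06 0.5995 0.99999             8
```

Each decline rate is the (positive) OLS slope of oxygen on time within one
closed measurement phase; `scaled_mo2` is the background-corrected,
mass-standardized consumption. The fitted intercept recovers the programmed
SMR to ~0.1 %, MMR is the highest per-step rate, AS is their difference,
and U_crit is recovered exactly because fatigue time is logged without
noise.

Tissue metrics work from long residue tables:

```r
coh <- simulate_cohort(cohort_truth(), seed = 1)
tox <- pipeline_toxicokinetics(coh$residues, coh$fish)
head(tox$shares)      # percent shares sum to 100 per fish and compound
fold_change_range(c(25.8, 56.5), c(1470, 1530))$rounded
#> min max
#>  26  59
```

A thin command-line wrapper with `simulate`, `respirometry`, `toxico`,
`endpoints` and `stats` subcommands is provided in
`inst/scripts/pfascope.R`.

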