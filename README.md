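# ocor

Total haemoglobin mass from the optimized carbon-monoxide rebreathing
method (oCOR), built for clinical cohorts with deranged plasma volume —
the motivating case is chronic liver disease with ascites, where a low
haemoglobin concentration may mean plasma-volume expansion rather than
true haemoglobin deficit.

In an oCOR test the subject rebreathes a known CO volume for 2 minutes;
the CO binds circulating haemoglobin, and the rise in carboxyhaemoglobin
from baseline to the "7-min value" (the mean of the 6- and 8-min venous
readings) measures the dilution of the bolus into the whole Hb pool:

    tHb-mass (g) = M_CO(t) × 100 / (ΔCOHb%(t) × 1.39)

with M_CO(t) the administered dose corrected for apparatus residual,
exhaled CO, and CO diffused to myoglobin at sampling time t, and 1.39 ml/g
the Hüfner constant. Blood, red-cell and plasma volumes follow from [Hb]
and hematocrit through the 0.91 cell factor.

The package covers the full workflow:

* **dose planning** — `recommend_dose()`: sex/training-status base doses
  with anemia, performance-status, polycythemia and ideal-body-weight
  rules, each step traced;
* **core calculation** — `thb_mass_at()`, `thb_timecourse()`: tHb-mass at
  any sampling time with time-dependent loss corrections;
* **volume derivatives** — `volume_set()`: BV / RCV / PV;
* **QC gating** — `validate_session()`, `filter_cohort()`: the ΔCOHb ≥ 4%
  validity rule plus peak/band/dose warnings;
* **stability statistics** — `paired_contrast()`,
  `repeated_measures_anova()`, `mann_whitney()`: does a sample drawn at
  10–20 min give the same mass as the 7-min value?
* **synthetic cohorts** — `simulate_cohort()`: seeded wash-in generator
  with per-subject ground truth for error quantification;
* **study reproduction** — `reproduce_study()`: recomputes the published
  cohort summaries from a packaged per-patient fixture.

## Worked example

```r
library(ocor)

subj <- ocor_subject("pt01", "male", weight_kg = 80, height_cm = 178,
                     hb_g_l = 104, performance_status = 2,
                     training_status = "debilitated")
recommend_dose(subj)
#> <dose_recommendation: 0.6 ml/kg x 80.0 kg -> 48 ml>
#>  - base male debilitated: 0.8 ml/kg
#>  - anemia ([Hb] 104 g/l): -0.1 ml/kg
#>  - performance status 2 >= 2: -0.1 ml/kg
```

An anemic, deconditioned 80-kg man gets 0.6 ml/kg instead of the 0.8 ml/kg
untrained-male base: 48 ml of CO. After the test, the timed COHb readings
(duplicate readings per draw; `time_min = -1` marks the baseline draw)
give the mass:

```r
sess <- ocor_session("pt01", dose_co_ml = 48,
  samples = data.frame(
    time_min = c(-1, -1, 6, 6, 8, 8, 20, 20),
    cohb_pct = c(1.5, 1.6, 6.6, 6.7, 6.7, 6.6, 6.4, 6.5)),
  residual_system_co_ml = 5.8, exhale_rate_ml_per_min = 0.17)

thb_mass_at(sess, 7)          # the canonical 7-min estimate
#>   time_min delta_cohb_pct absorbed_co_ml thb_mass_g flags
#> 1        7            5.1          40.76        575

volume_set(575, hb_g_l = 104, hct = 0.31)
#>    bv_ml rcv_ml  pv_ml cell_factor
#> 1 6075.7   1714 4361.7        0.91
```

The rise of 5.1% sits in the 4.0–6.5% target band (`validate_session()`
reports the session valid with no flags), 40.8 ml of the 48 ml dose is
bound to circulating Hb at 7 min, and the subject's 575 g of haemoglobin
is suspended in a 6.1 l blood volume of which 4.4 l is plasma — a picture
consistent with dilutional anemia. A 20-min sample gives 550 g, 4% lower:
single readings drift, which is why the stability analysis works on
cohorts, not individuals.

The `analysis/` scripts run the package's own studies end to end:

* `01_reproduce_study.R` — recomputes every published cohort summary from
  the packaged fixture (all 16 reproduce, including the 0.73 ml/kg mean
  dose, 647.3 g mean tHb-mass, 77% anemia prevalence, 3 of 16 exclusions
  and the 4.1 g 7-vs-20-min difference);
* `02_synthetic_cohort.R` — one simulated n = 13 cohort through the whole
  pipeline;
* `03_parameter_recovery.R` — inversion is exact without noise and
  recovers tHb-mass with ≈2% relative SD and negligible bias under
  realistic hemoximeter noise;
* `04_stability.R` — across 200 simulated cohorts the 7-vs-20-min
  difference stays under 1% of the cohort mean and the repeated-measures
  ANOVA finds no time effect in ≈9 of 10 replicates.

See `vignettes/ocor-methods.Rmd` for the models, parameter defaults and
design choices.

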