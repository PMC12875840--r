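# slnbcea

A Markov cohort cost-utility model of neck management strategies in early
(cT1T2N0) oral squamous cell carcinoma, from the payer perspective of
India's PM-JAY national insurance scheme. The package is aimed at health
economists and HTA analysts who want a fully tested, scriptable
re-implementation of this decision problem: every quantity — the
decision-tree stratification, the cohort trace, the economic outcomes and
all sensitivity analyses — is an ordinary R function over an explicit,
validated parameter set.

Three strategies are compared:

* **Group I** — sentinel lymph node biopsy (SLNB) with intraoperative
  frozen section; node-positive patients get a modified neck dissection
  (MND), false negatives are readmitted for MND;
* **Group II** — elective neck dissection (END) alone: selective neck
  dissection (SND) for everyone;
* **Group III** — END with frozen section: SND upgraded to MND when the
  frozen section is positive.

## Model core

A decision tree splits each strategy into diagnostic strata
(TP/FP/TN/FN from prevalence `p`, sensitivity `se` and negative predictive
value `NPV`: `tp = p·se`, `fn = p(1−se)`, `tn = NPV·fn/(1−NPV)`,
`fp = 1 − tp − fn − tn`). Each stratum then enters a six-state annual-cycle
Markov model — disease-free (DFS), loco-regional recurrence (LRR),
salvaged, distant metastasis (DM), cancer death, other-cause death — run
to age 100 from entry at age 50, with age-banded background mortality,
trapezoidal half-cycle correction and 3% annual discounting of costs,
life-years and QALYs. Strategies are ranked by QALYs and compared by
incremental cost-utility ratio,

ICUR = ΔC / ΔQ  (INR per QALY),

with incremental net monetary benefit INMB = λ·ΔQ − ΔC at the
willingness-to-pay λ = INR 211,725/QALY (one-time GDP per capita).
Uncertainty is handled by one-way deterministic sensitivity analysis
(tornado), 1000-iteration probabilistic sensitivity analysis with
method-of-moments beta/gamma/normal/Dirichlet distributions (CE plane and
CEAC), and a threshold sweep of the occult-metastasis rate. An
independent patient-level microsimulation (`simulate_patients()`) serves
as a brute-force oracle for the cohort engine.

## Worked example

```r
library(slnbcea)

params <- table1_defaults()       # the published parameter fixture
bc <- base_case(params)           # all three strategies + ICUR ladder
bc$ladder
```

```
 group total_cost total_qaly delta_cost delta_qaly     icur     inmb dominance
   III   184161.0   8.255333         NA         NA       NA       NA      <NA>
    II   170524.5   8.329254  -13636.51 0.07392137       NA 29287.52  dominant
     I   190242.2   8.645186   19717.73 0.31593141 62411.43 47172.85      none
```

Strategies are ordered by increasing QALYs. Under this parameterisation
END alone dominates END+FS (cheaper *and* more effective, because the
frozen-section false positives carry MND costs and MND disutility), so
SLNB's relevant comparison is against END alone: ≈0.316 extra QALYs for
≈INR 19,718 extra lifetime cost, ICUR ≈ INR 62,411/QALY — far below the
WTP threshold, with INMB ≈ INR 47,173 per patient.

```r
s <- survival_summary(bc$results$I$trace, 5)
round(100 * c(os = s$os, os_excl_dm = s$os_excl_dm, dfs = s$dfs), 2)
#          os os_excl_dm        dfs
#       80.66      79.33      72.65
```

`os_excl_dm` (alive without distant disease) is the readout matching the
conventionally quoted five-year survival for this model; disease-free
survival is identical across strategies by construction.

```r
ts <- threshold_sweep(params)     # sweep occult rate, SLNB vs END alone
ts$breakpoint
# [1] 0.53
```

SLNB stays cost-effective at the WTP threshold up to an occult-metastasis
rate of 0.53 (grid step 0.01).

## Analysis workflow

The numbered scripts under `analysis/` run the full study and write CSV
tables plus a JSON run manifest (configuration, seed, calibration knobs,
output list) under `results/`:

```sh
Rscript analysis/01_base_case.R      # lifetime + 5y/10y scenario tables, survival curves
Rscript analysis/02_one_way_dsa.R    # tornado tables (I vs II, I vs III)
Rscript analysis/03_psa.R            # 1000-draw CE plane and CEAC
Rscript analysis/04_threshold.R      # occult-metastasis breakpoint
```

## Parameter files

`save_parameter_set()` / `load_parameter_set()` serialise the full
parameter set (accuracies, utilities, transitions, costs, analysis
configuration and distribution assignments, all costs in INR) as JSON with
strict validation — unknown keys are rejected and every violation is
reported with its field name. `validate_parameters()` returns the full
violation table without raising. See the methods vignette
(`vignettes/cost-utility-model.Rmd`) for the model's assumptions,
calibration knobs and limitations.
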