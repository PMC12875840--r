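---
title: "A Markov cohort cost-utility model of neck management in early oral cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of neck management in early oral cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The decision problem

In clinically node-negative early oral squamous cell carcinoma (cT1T2N0),
roughly a quarter of patients harbour occult nodal metastasis. Elective neck
dissection (END) treats everyone surgically and overtreats the node-negative
majority, with appreciable shoulder morbidity; sentinel lymph node biopsy
(SLNB) aims to restrict neck dissection to the patients whose sentinel node
is positive. `slnbcea` implements a decision-tree-plus-Markov cost-utility
model comparing three strategies from the payer perspective of India's
PM-JAY insurance scheme:

* **Group I** — SLNB with intraoperative frozen-section analysis; positive
  sentinel nodes trigger a modified neck dissection (MND) in the same
  admission, false negatives are readmitted for MND after final
  histopathology;
* **Group II** — END alone: selective neck dissection (SND, levels I–III)
  for everyone;
* **Group III** — END with intraoperative frozen section: SND extended to
  MND when the frozen section is positive.

Outcomes are discounted lifetime costs (INR), life-years (LY) and
quality-adjusted life-years (QALYs); strategies are compared through
incremental cost-utility ratios (ICUR) on a dominance-ordered ladder and
through incremental net monetary benefit (INMB) at a willingness-to-pay of
one-time Indian GDP per capita (INR 211,725 per QALY).

## Decision tree

Each strategy is expanded into diagnostic strata by
`stratify_from_sens_npv()`, which solves the 2×2 diagnostic table from the
occult-metastasis prevalence $p$, test sensitivity $se$ and negative
predictive value $NPV$:

$$tp = p\,se,\qquad fn = p(1-se),\qquad tn = \frac{NPV\,fn}{1-NPV},\qquad
fp = 1 - tp - fn - tn.$$

Not every $(p, se, NPV)$ triple is feasible: the implied $tn$ may exceed
$1-p$. The exported stratifier raises an error in that case; inside the
model (`pathway_profiles()`), sampling and sensitivity-analysis contexts use
a clamped mode that caps the NPV at its feasible maximum (setting $fp = 0$)
and counts the event. At the base-case inputs the triple is exactly
feasible and the clamp is inert.

Each stratum carries an upfront cost (surgery packages, plus a
radiotherapy ± chemotherapy adjuvant bundle for strata that are
node-positive on final histopathology), a neck-dissection status
(which selects dissected/undissected recurrence dynamics), a
recurrence-risk class driven by final histopathology — not by the test
result — and a utility track. Group III false negatives keep their SND and
receive adjuvant therapy only; a toggle
(`costs$group3_fn_readmission_mnd`) converts them to an MND readmission for
scenario exploration.

## Markov structure

Six health states: disease-free survival (DFS), loco-regional recurrence
(LRR), salvaged (post salvage surgery), distant metastasis (DM), death from
oral cancer, death from other causes. Cycles are annual; the cohort enters
at age 50 and the lifetime horizon runs to age 100 (50 cycles). Annual
cancer-specific transition probabilities come from the published parameter
table; the LRR-to-cancer-death probability is the annual equivalent of an
85% two-year mortality ($1-(1-0.85)^{1/2} = 0.6127$) and the DM exit
assumes exponential survival with a 7.5-month median
($1 - 0.5^{12/7.5} = 0.6701$). Age-dependent all-cause mortality (five-year
bands from a national life table) is added as a competing exit from every
alive state; the printed band sequence is non-monotone between ages 71–75
and 76–80 and is applied exactly as printed. Ages at or below 50 use the
first band; age 80 falls in the closed 76–80 band.

Competing risks are combined additively within a row (cancer exits plus
background mortality, remainder stays). If a row's exits exceed unit mass —
possible only when extreme bound values meet the 0.151 mortality band —
the row is renormalised and a warning emitted.

## Accrual conventions

* **Half-cycle correction** is the trapezoidal (life-table) rule: each
  cycle's LY, QALY and state-occupancy costs use the mean of start- and
  end-of-cycle membership. A cohort facing a 50% annual death probability
  therefore accrues exactly 1.5 undiscounted life-years, and certain death
  in the first cycle accrues 0.5 — both are closed-form test anchors.
* **Cycle 0**: upfront surgical and adjuvant costs fall at model entry,
  undiscounted and without half-cycle correction.
* **Event-linked costs** are charged in full on the transition flow:
  recurrence treatment on entry into LRR (from DFS or from the salvaged
  state), salvage surgery on entry into the salvaged state.
* **Per-cycle costs**: follow-up investigation panels while in DFS, basic
  supportive care while in DM (the per-cycle reading of palliative-care
  cost; a one-off alternative would attach it to the DM entry flow).
* **Discounting** at 3% per year, factor $1/(1.03)^t$ for cycle $t$,
  applied to costs, QALYs and LYs alike.

Utilities: the DFS utility depends on the pathway. SLNB true negatives
(no neck dissection) keep the post-resection utility 0.891 throughout.
Neck-dissection tracks use a morbidity-weighted mix of the with/without
shoulder-morbidity utilities for their procedure (SND or MND) during the
first five model years — the post-surgical utility window — after which
quality of life settles at the generic post-neck-dissection utility 0.819
regardless of dissection extent. The morbidity weight defaults to 0.17,
the midpoint of the 9–25% shoulder-morbidity range reported after
selective dissection; it is an exposed knob. LRR, DM and salvaged states
use their tabulated utilities (0.659, 0.508, 0.264).

## Treatment-mix calibration knobs

The source parameter table prices individual packages but does not state
the mix with which they are used. These quantities are therefore exposed
as calibration knobs, fixed once against the published lifetime cost
totals and recorded in every run manifest:

| knob | default | reading |
|---|---|---|
| `adjuvant_chemo_fraction` | 0.5 | half of adjuvant/recurrence RT courses add concurrent chemotherapy |
| `chemo_cycles` | 6 | weekly cisplatin cycles per chemoradiation course |
| `rt_modality_weights` | (0.10, 0.70, 0.20) | 2D-EBRT / 3D-CRT / IMRT shares of RT courses |
| `lrr_salvage_fraction` | 0.25 | recurrences managed with upfront salvage surgery rather than RT±CT; kept low because the state structure also charges explicit salvage surgery on the LRR→salvaged transition |
| `followup_visits_per_year` | 4, 4, 2, 2, 2 then 1/year | surveillance visit schedule while disease free |
| `radiology_per_visit` | 0.9 | high-end radiology investigations per follow-up visit (labs at every visit) |

The lab panel per visit is CBC + liver function + renal function +
electrolytes + TSH at CGHS rates.

## Probabilistic sensitivity analysis

Each parameter's 95% interval is converted to a standard deviation with
the normal-theory divisor 3.92; distributions are fitted by method of
moments — beta for probabilities and utilities, gamma for costs, normal
for the lab tariffs, point masses for fixed quantities. The printed
interval for the SLNB package rate is degenerate (identical bounds) and is
treated as a printing error: the working bounds are ±20% of the base rate,
with the printed values kept as fixture metadata.

Transition probabilities labelled Dirichlet are grouped into one block per
source health state (DFS node-positive, DFS node-negative, LRR, salvaged);
each block plus its stay remainder is drawn jointly from a Dirichlet whose
common concentration is set so the marginal standard deviations match
their CI-implied values on average. Where dissected and undissected
variants share a source state they are carried in the same block, so each
draw remains a valid sub-distribution for either pathway.

Draws are post-processed to preserve invariants: probabilities clipped to
[0,1], with-morbidity utilities capped at their without-morbidity
counterparts, and jointly infeasible diagnostic triples resolved by the
NPV clamp described above (with upper NPV bounds of 0.98–1.00 and an
occult-rate distribution centred at 0.23, roughly half of the 1000 draws
touch at least one clamp; the count is recorded on the PSA output).
CE-plane probabilities use the INMB criterion rather than the ICUR
quadrant rule, which is robust to draws with negative incremental QALYs.

## Threshold analysis

The occult-metastasis sweep re-derives the diagnostic strata at each grid
value. Sensitivity and the *base-implied specificity* are held fixed and
the NPV is recomputed from the swept prevalence: NPV is
prevalence-dependent by definition, and holding it fixed at 0.93 would
make the 2×2 infeasible for prevalences beyond ≈0.28, well inside the
0.05–0.95 sweep. Cost-effectiveness at each grid point is judged by INMB
at the configured willingness-to-pay; the reported breakpoint is the
largest cost-effective grid value, together with the grid resolution. The
default comparator is END alone — SLNB's predecessor in the base-case
dominance ladder, i.e. the comparison whose ICUR is "the Group I ICUR" in
the dominance table; the sweep can equally be run against END+FS.

## The microsimulation oracle

`simulate_patients()` is an individual-level Monte Carlo simulator over
the same stratum weights and transition matrices but with independently
written accrual code (its own per-patient trapezoid, event-cost and
discounting logic). It is the package's brute-force correctness check: for
every strategy, cohort-engine totals must lie within three Monte Carlo
standard errors of microsimulation means — on the published inputs with
200,000 patients and on five randomised valid parameter fixtures
(`random_parameter_fixture()`) with 100,000 patients each. Empirical state
occupancy is also checked against the cohort trace within binomial error.
These sizes put the standard error of mean QALYs near 0.01, tight enough
to detect a missed half-cycle or an unaccrued state at base-case scale.

## Numerical choices and degenerate inputs

* Mass conservation is asserted at 1e-10 per cycle; membership is exactly
  non-negative by construction.
* Exit sums within 1e-9 of unity are renormalised silently (pure floating
  point); larger overshoots warn.
* QALY ties in the ICUR ladder are broken on cost and flagged; dominated
  or dominant comparisons report a flag instead of a (meaningless
  negative) ratio. Tornado bars, in contrast, keep the raw cost/QALY ratio
  so that bounds producing dominance still plot.
* `validate_parameters()` is total — it returns a violation table rather
  than raising, so a configuration file's problems are reported all at
  once; `load_parameter_set()` rejects unknown keys.

## What the model's survival output means

With the published inputs the model's five-year "overall survival"
figures that match the values quoted for this analysis (79.32% / 78.98%)
are obtained from the fraction alive *without distant disease*
(`os_excl_dm`, i.e. excluding the DM compartment), not from the plain
non-death fraction (which is ≈1.3 points higher). `survival_summary()`
therefore returns both readouts. Life-years and QALYs, by contrast, accrue
DM occupancy in full (utility 0.508, supportive-care cost per cycle),
which is the internally consistent treatment of a state the parameter
table prices and values explicitly.

## Known limitations

* The model is not sub-site specific; diagnostic accuracy of SLNB differs
  between, e.g., buccal mucosa and floor-of-mouth primaries, and the
  pooled accuracy inputs average over that variation.
* Recurrence risk after surgery is driven by nodal status alone; depth of
  invasion, margins, perineural invasion and other pathological risk
  factors are not modelled, and second primaries and treatment-toxicity
  states are out of scope.
* The implied frozen-section specificity in the END+FS arm (≈0.64 from the
  tabulated sensitivity and NPV at 23% prevalence) is clinically low and
  places a large false-positive stratum on the MND pathway; this makes the
  END+FS arm dearer and less effective than END alone here, and the
  resulting dominance pattern — and every quantity downstream of the
  I-versus-II cost gap, including the occult-rate breakpoint — is
  sensitive to that stratification. The diagnostic inputs are taken at
  face value.
* Treatment-mix knobs are calibration choices, not observed quantities;
  conclusions about absolute costs inherit their uncertainty, while
  within-pair incremental costs are essentially knob-independent.
* The synthetic fixtures used by the property tests randomise rates,
  utilities and costs within clinically plausible ranges but keep the
  model's structural assumptions (annual cycles, additive competing risks,
  exponential DM survival); passing tests demonstrate internal
  correctness of the engine, not external validity of the model for any
  real cohort.
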