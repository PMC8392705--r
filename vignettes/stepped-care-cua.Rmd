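---
title: "Methods: a cost-utility model of collaborative stepped care for depression and anxiety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cost-utility model of collaborative stepped care for depression and anxiety}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steppedcea)
```

## The decision problem

`steppedcea` compares two ways of treating adults who consult their GP
for depression and/or anxiety over one year, from a health-sector
perspective in 2019 Australian dollars:

* **Collaborative stepped care (CSC).** Mild cases receive nurse-guided
  self-help at the GP clinic (branch CSC1a); moderate cases the same plus
  antidepressants (CSC1b); severe cases enter specialised mental
  healthcare directly. Patients who have not remitted 4 months after
  starting step 1 step up to specialised care, where they receive
  antidepressants, psychotherapy or both (CSC2a/2b/2c). Training of
  providers (CSC0) and a benzodiazepine add-on prescribed to a proportion
  of all patients (CSC9) run across the 8-month delivery period.
* **Care-as-usual (CAU).** A baseline split across antidepressants only
  (CAU1), referral to specialised care (CAU2) and no treatment (CAU3,
  which also absorbs dropouts), plus a benzodiazepine add-on (CAU9).

The structure is a quasi-decision tree: a cohort model whose branches are
fixed at baseline severity and whose only time dynamics are the 4-monthly
remission transitions. Comorbid patients carry a single primary
diagnosis, so the depression and anxiety streams are additive and the
model can target `both`, `depression_only` or `anxiety_only`.

## Health outcomes

Remission probabilities are supplied per arm, disorder and 4-month
interval (0–4, 4–8, 8–12 months). The package reads them as
**conditional** per-interval probabilities among the still-unremitted:
starting from $U_0$ eligible persons, $U_t = U_{t-1}(1-p_t)$, which keeps
counts monotone for any input. The alternative reading — cumulative
proportions remitted by the end of each interval — is available via
`propagate_remission(..., method = "cumulative")`; we default to the
conditional reading because it is the only one that is internally
consistent for arbitrary probability triples. Remission is absorbing
within the year: no relapse, no mortality, and with a 1-year horizon no
discounting.

Person-time in the remitted and unremitted states is accumulated by
area-under-the-curve with the **midpoint convention**: a person remitting
within an interval contributes half of it (1/6 year) to each state. This
equals the trapezoid rule on the piecewise-linear unremitted-count curve,
and the test suite checks both that identity and agreement with a
200 000-individual microsimulation.

Health gain uses the inverted DALY formula $(1-\mathrm{DW})\times
\mathrm{LY}$, summed over the two states, so larger values mean more
healthy-equivalent time ("DALYs averted"). Condition weights (by disorder
and severity) are first combined multiplicatively with a background
morbidity weight, $\mathrm{DW}_{adj} = 1-(1-\mathrm{DW}_c)(1-\mathrm{DW}_b)$,
the standard independence assumption for co-occurring health losses. The
remitted state carries a small residual weight (default 0.01 in the
synthetic set) bounded above by the mildest unremitted weight.

## Costs and the incremental analysis

Every branch cost is `unit_cost × quantity × coverage × persons`, with
persons per branch derived from the severity distribution and 4-month
non-remission (step-up) counts. Choices that were genuinely open:

* **Training (CSC0)** is amortised per treated person, reflecting
  steady-state operation; `training_mode = "fixed_program"` charges it
  once instead.
* **Step-2 costing**: severe patients are costed at step 2 from month 0;
  mild/moderate step-up entrants are costed there for the 4–8 month
  window (their step-1 course has already been costed in full).
* **Cost offsets** are the annual treatment cost per unremitted case
  times the difference in unremitted burden between arms. The default
  burden is unremitted *person-years*, consistent with the AUC outcome
  engine; `offset_basis = "cases_12m"` switches to cases still unremitted
  at 12 months, since "treatment costs for unremitted cases" admits both
  readings.
* **Time and travel costs** are excluded from the base case. Each branch
  records a visit count, and scenario SA2 values all visits at the
  `TIME_TRAVEL` per-visit unit cost in both arms.

Net incremental cost is pathway cost difference plus offsets; dividing by
incremental DALYs averted gives the ICER, judged against a
willingness-to-pay of A$50 000/DALY. `classify_icer()` implements the
plane conventions: north-east → numeric ICER, south-east → *dominant*,
north-west → *dominated*, south-west → numeric (read from the SW
convention). Boundary ties go to the more favourable label so quadrant
proportions are reproducible; a zero incremental effect yields
"equivalent"/"indeterminate" rather than an infinite ratio.

## Uncertainty analysis

`run_psa()` draws every uncertain parameter independently each iteration
(the schema records no correlation structure), re-runs the full pipeline
and records (ΔC, ΔE). Implementation choices:

* One master seed; per-iteration substreams are derived deterministically
  so results do not depend on execution order.
* Severity splits and allocation proportion sets are drawn marginally
  from their betas and renormalised to sum to 1 — the standard
  moment-preserving shortcut when a joint (Dirichlet-type) specification
  is unavailable.
* A draw violating the remitted-weight ordering is rejected and redrawn,
  with the count reported (`n_rejected`).
* 95% uncertainty intervals use type-7 (inclusive linear interpolation)
  percentiles. ICER percentiles are not well-defined across quadrant
  changes, so `summarise_icer_ui()` orders draws as *dominant* < numeric
  ICER < *dominated* and reports labelled endpoints when a percentile
  position falls on a labelled draw — reproducing the "dominant to
  ⟨number⟩" reporting style.
* Cost-effectiveness at threshold λ is defined by net monetary benefit
  λ·ΔE − ΔC ≥ 0, which handles all four quadrants coherently; the CEAC is
  this probability over a λ grid. It is non-decreasing in λ whenever all
  draws have ΔE ≥ 0, which the property tests assert exactly in that
  regime.

The univariate tornado (`tornado()`) perturbs one point estimate at a
time by ±10%, leaving uncertainty families untouched. A perturbed
proportion deliberately unbalances its sum-to-1 set, so tornado re-runs
validate without the strict sum checks; for a cost line entering ΔC
additively the swing has the closed form $0.2c/\Delta E$, which the suite
verifies to 1e-9 relative.

## The synthetic parameter generator

Real deployments of such models are driven by tabulated input data:
demographic cohorts, adjusted prevalences, severity distributions, trial
remission probabilities, and unit-cost schedules with their uncertainty
specifications. `generate_parameters()` emulates exactly that structure
so the pipeline is fully exercisable without any external file. Its
defaults are the package's reference study conditions:

* 12 age–sex cohorts (six adult bands, populations ~0.9–1.7M declining
  with age), GP mental-health consultation ~13% (women) / ~9% (men),
  primary-diagnosis prevalences ~28% (depression) and ~33% (anxiety)
  among consulters, severity splits near 50/35/15.
* CAU remission per interval (0.35, 0.30, 0.25) for depression and
  (0.30, 0.25, 0.20) for anxiety, with CSC higher by an additive
  advantage (default 0.15) in every interval — the scale of first-step
  benefit reported for collaborative stepped care trials.
* GBD-2019-style disability weights (e.g. moderate depression 0.396),
  background morbidity 0.08, residual remitted weight 0.01.
* Unit costs (2019 A$): guided self-help ~350–430 per course, step-2
  treatments 250–1000, annual treatment cost per unremitted case 2000,
  time/travel A$25 per visit.
* Beta uncertainty on all probabilities/proportions and gamma on all unit
  costs, moment-matched to the point with a single spread dial
  (default CV ≈ 0.12).

These magnitudes are chosen once as realistic for the setting and land
the base-case ICER in the low-thousands A$/DALY region, so the plane and
CEAC code paths resemble a genuinely favourable-but-not-free
intervention; they are documented as synthetic and are not any study's
estimates. What the generator does **not** emulate: correlation between
parameters, age- or sex-specific remission, time-varying CAU allocation,
relapse, or severity change short of remission — so green tests
demonstrate correctness of the machinery, not real-world
cost-effectiveness.

## Numerical conventions and problem sizes

Person counts stay real-valued throughout (rounded only in reports);
currency is never rounded internally. Validation enforces sum-to-1
constraints at 1e-9, the remitted-weight ordering at 1e-12, and names the
offending field in every error. The packaged test suite runs the Monte
Carlo engine at 40–200 iterations and the distribution-moment checks at
100 000 draws; `scripts/acceptance.R` runs the full 3000-iteration
analysis, which completes in well under a minute on one core.

## Known limitations

The model inherits the structural limits of its class: a single year, two
health states per disorder, no productivity costs, no treatment effects
short of remission, and remission probabilities treated as transportable
across settings. The ICER uncertainty interval depends on the documented
plane ordering; alternative conventions (e.g. iteration-wise ICER
percentiles) can differ when draws change quadrant.
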