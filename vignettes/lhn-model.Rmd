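---
title: "The lhnsim model: agents, knowledge dynamics, and experiment design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lhnsim model: agents, knowledge dynamics, and experiment design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhnsim)
```

# The system being modeled

A collaborative Learning Health Network (LHN) is a healthcare organization
in which patients, clinicians, and care centers share data and knowledge to
improve outcomes for a chronic condition. `lhnsim` implements a
discrete-time agent-based model of such a network. Patients (assigned to
clinicians within care centers) carry a health status in [0, 1], a latent
phenotype that determines how well each available treatment would work for
them, and an ordinal engagement state on the ladder

> unaware (0) → aware (1) → participating (2) → contributing (3) → owning (4).

Clinicians carry the same engagement ladder. Two undirected influence
networks (patient–patient and clinician–clinician) spread engagement;
clinical encounters, scheduled every `encounter_period` steps, are where
knowledge is exchanged, treatments are evaluated and switched, and
knowledge is contributed to a shared commons. Two care-center level
interventions modulate the system: pre-visit planning (PVP), which caps the
usable fraction of decision knowledge at 0.2 / 0.5 / 1.0 for low / medium /
high; and an enhanced registry (ER), which at level medium uploads one
record per encounter for periodic analysis into commons items, and at level
high additionally makes data available in real time at the encounter
(flooring the clinician's effective information access at the
'participating' level).

Time steps are weeks (`steps_per_year = 52`); the reference horizon is five
years (260 steps); the reference cohort is closed: 4 centers × 5 clinicians
× 10 patients = 200 patients. Probabilities described on an annual scale
(peer influence, burnout) are converted with
`p_step = 1 − (1 − p_annual)^(1/52)` so that compounding over a year
reproduces the annual rate.

# Knowledge: the commons, PRI, IRI, and praxis

The commons is a pool of exchangeable knowledge items whose usefulness
decays exponentially with half-life `shared_knowledge_half_life`; its
effective stock is `S(t) = Σ_i 2^(−(t − t_i)/hl)`, maintained
incrementally. Agents at level contributing or above add an item per
encounter with probability given by their contribution determiner; the
registry pipeline converts accumulated records to
`floor(records / enhanced_registry_record_per_commons_item)` items at every
analysis period. The *number of items in the commons* therefore rises with
contribution and falls as items age out; the `knowledge` outcome of a run
is the change in this effective count. The cumulative number of items ever
added (`items_added`) is also reported; unlike the stock it is invariant to
the decay half-life when engagement is held fixed.

Two information stocks feed decision making:

* **Phenotype response information (PRI)** — what the pair knows about how
  this phenotype responds to the available treatments, drawn from the
  commons. At an encounter the accessible knowledge is
  `A = S × phenotype_realization × mean(access)`, and PRI closes a fraction
  `1 − exp(−u·A)` of its remaining gap to 1. PRI does not decay on its own;
  phenotype knowledge ages only through the commons stock.
* **Individual response information (IRI)** — what the pair knows about
  this patient's own response to the current regimen. IRI decays with
  half-life `patient_response_info_half_life` and gains
  `Δ · (1 + a) · mean(access)` per encounter, where
  `a = min(a_max, a_unit · S)` is the shared-knowledge acceleration.
  The gain is scaled by the mean patient/clinician access fraction because
  individual response information is coproduced: how much of it is captured
  depends on both parties' engagement. Patients also start with an initial
  endowment IRI ~ Uniform(0, 0.4): people living with a chronic condition
  arrive knowing something about their own treatment response.

Access is engagement-gated and anchored at the participating level by the
degree parameters: unaware 0, aware `0.25 d`, participating `d`,
contributing `min(1, 1.5 d)`, owning `min(1, 2 d)`.

**Praxis** — knowledge actually available for the treatment decision — is
the equal-weight mean of the capped stocks:
`praxis = ½ min(PRI × mean_access, cap) + ½ min(IRI, cap)`, with `cap` the
PVP cap. Equal weights are the default because both stocks feed the
decision with no stated priority; the weight is an argument of
`compute_praxis()`.

# The clinical encounter

Stages, in order: (1) engagement update — an unaware patient meeting an at
least aware clinician becomes aware with `encounter_aware_determiner`; a
patient meeting a strictly more (less) engaged clinician moves up (down)
one level with the activate (dispirit) determiner, at most one transition
per encounter. (2) Knowledge access: PRI and IRI updates as above, with the
ER real-time boost where applicable. (3) Praxis. (4) Evaluation: the pair
judges whether the treatment is working. The true verdict is
`Δh > −tolerance` since the previous encounter — a regimen that holds
health within the tolerance band (absorbing noise and a recoverable
relapse) counts as working, one under which health genuinely declines does
not. The verdict is flipped with probability `e0 · (1 − praxis²)`, where
`e0` is the zero-praxis misjudgment probability (the "reversed" accuracy
axis). The praxis response is concave: misjudgment falls off slowly at
first, and only consolidated knowledge drives it toward zero. (5) If this
is the first encounter, or the verdict is "not working", a treatment is
selected: candidates (all treatments at first, all but the current one at a
switch) are ranked by true target health and the rank-r candidate among m
receives weight `E^((m−r)/(m−1))`, with `E = 1 + (E_max − 1) · praxis`.
`E = 1` is uniform ignorance; large `E` concentrates on the best-matched
treatment. (6) Knowledge contributions and the registry record. (7) The
next encounter is scheduled.

# Health dynamics

Each step, every treated patient's health follows

```
h' = clip( h + κ · r(h) · (T − h) − relapse + N(0, σ), 0, 1 )
```

* `T` is the current treatment's target for the patient's phenotype;
  targets per phenotype are the evenly spaced grid from `best_target`
  (0.85) down to `worst_target` (0.25), permuted independently per
  phenotype over `n_treatments = 5` treatments.
* `r(h) = max(0.3, 4h²)` is a *reserve* factor: response to treatment
  scales with the patient's physiological reserve, so decline into poor
  health is increasingly hard to reverse, while recovery accelerates once
  health is restored. The floor keeps the well-matched treatment able to
  rescue a deteriorated patient — barely — while mismatched regimens
  cannot.
* Relapses remove `relapse_magnitude` (0.15) with per-step probability
  `relapse_probability × min(1.5, ((1.1 − h)/0.6)²)`: exacerbation risk
  rises as the condition worsens and nearly vanishes in well-controlled
  patients, the standard picture for relapsing chronic disease.
* `natural_history_drift` is 0 by default and `σ = 0.01`.

These constants are the model's held-fixed condition description. They were
chosen, once, so that the three reference network configurations span the
intended regimes: a poorly functioning network (selection ceiling 10,
misjudgment 0.20) *loses* about 0.1 of health over five years, a
middling one (200, 0.10) holds steady, and a high-functioning one
(1000, 0.001) gains about 0.15. The mechanism that separates these regimes
is the interaction of churn and skill: relapses and misjudgments force
treatment re-selection, so long-run health tracks how reliably the network
puts patients back on their best-matched regimen, and the reserve factor
makes sustained mistakes compound into crashes that only well-informed
selection can rescue.

# Initial conditions

Initial health is Uniform(0.3, 0.7). Engagement starts unaware except for a
founding cohort: 30% of clinicians at owning (LHNs are typically
clinician-initiated), 12% of patients at participating, plus a 3% nucleus
of owning patients. The nucleus matters structurally: peer influence and
encounter activation both require a strictly more engaged partner, so
without any agent above 'participating' the contributing levels — and with
them all knowledge contribution — would be unreachable. Commons items
present at t = 0 (`shared_knowledge_initial`) are created at age zero;
registry preloads count toward the first scheduled analysis.

# The parameter ranges file

The packaged ranges (`inst/extdata/ranges_default.yaml`) define the
sampling space for the sensitivity analysis and, through their midpoints,
the default parameter values. They are the package's own declared choices,
set to spans a practitioner would defend for each quantity:

* encounter and registry-analysis periods: 11–13 weeks (protocolized
  roughly quarterly follow-up);
* engagement-transition probabilities: occasional, not routine — dispirit
  determiners up to 0.2, annual burnout up to 0.1, annual become-aware up
  to 0.3 (patients) / 0.15 (clinicians), patient encounter-activation up
  to 0.3, clinician peer-activation up to 0.6; patient peer-activation
  spans the full [0, 1] (it is the lever the network's community-building
  acts on);
* information-access degrees and phenotype realization: the full [0, 1];
* contribution determiners: 0.05–0.2 (agents contribute at a minority of
  encounters, never at none once engaged);
* commons half-life: 52–208 steps (knowledge stays useful one to four
  years); individual response information half-life: 13–130 steps;
* initial commons: 0–50 items; registry records per item: 18–30;
* selection efficiency maximum 10–1000 and zero-praxis misjudgment
  0.001–0.2, the spans exercised by the factorial experiment.

Wide, flat spans on the turnover probabilities would make engagement churn
the dominant driver of every outcome and mask the decision-quality and
knowledge-decay mechanisms the model exists to study; the narrower spans
keep each subsystem in a regime where its intended lever is the one that
moves it.

# Experiments

**Sensitivity (LHS-PRCC).** `run_sensitivity()` draws a Latin hypercube
design over the 30 parameters (one draw per equal-probability stratum per
margin; uniform or triangle marginals), runs one seeded five-year
simulation per row, and computes partial rank correlation coefficients of
every parameter against the three outcomes (health, praxis, knowledge) by
double residualization on ranks, with percentile bootstrap
confidence intervals at a Bonferroni-corrected level. A brute-force
normal-equations oracle and rank-invariance properties pin the PRCC
implementation exactly in the test suite. The reference design uses 1000
rows.

**Solution-space grids.** `grid_explore()` sweeps two parameters over 41
evenly spaced values each (1,681 cells), all other parameters held at their
range midpoints, averaging a chosen outcome over seeded replicates per
cell (default 3).

**Factorial intervention experiment.** `factorial_experiment()` crosses
network functioning (low/medium/high coordinates for selection efficiency
and evaluation accuracy) with PVP and ER levels — 27 cells, each summarized
by the ensemble median of median final patient health over 30 seeded
replicates. Two coordinate sets for the functioning levels ship as presets
(`"selection_sweep"`, the default, and `"regime_anchors"`); the
regime-anchor coordinates are the ones whose low/medium/high health
regimes match the declining / stable / improving contour anchors, so the
package's end-to-end checks use them.

# Numerical and design notes

* One RNG stream per run, seeded once: identical scenario + seed gives
  byte-identical output. Ensembles give replicate k the seed
  `base_seed + k`.
* Patients due in a step are processed in a freshly shuffled order;
  within-step updates use the step-start commons stock, and peer influence
  resolves against a snapshot of levels (no within-step cascades).
  Multiple qualifying neighbors grant a single Bernoulli trial per agent
  per step, so degree does not mechanically multiply transition rates.
* Peer influence is upward-only; encounter dispiriting and clinician
  burnout are the only downward forces.
* Ties in treatment ranking cannot occur (targets are strictly distinct by
  construction); ties in rank transforms use average ranks.
* A zero-or-degenerate residual regression in the PRCC is reported as `NA`
  with a warning, never silently zero.
* Cohort-exit rules (health thresholds, random exit) are implemented but
  disabled by default; all reference experiments use the closed cohort.

# What the synthetic scenarios do and do not show

All populations, effectiveness structures, and networks are generated
internally; there is no empirical calibration. The generator emulates the
*mechanisms* the theory describes — engagement contagion, knowledge
coproduction and decay, engagement-gated access, decision quality — under
idealized assumptions: exchangeable knowledge items, a single condition
with a fixed phenotype structure, Erdős–Rényi-like influence networks, no
demographics, costs, or comorbidity. Passing tests therefore certify the
implementation and the qualitative mechanism structure, not quantitative
predictions about any real network. The simulated experiments' problem
sizes (1000-row hypercube at 200 patients; 30 replicates per ensemble
cell) were chosen as the smallest at which the reported summaries are
stable across seeds.

# Known limitations

* The engagement ladder has no memory; an agent dispirited to unaware is
  indistinguishable from one never engaged.
* The commons is content-free: items are exchangeable units, so knowledge
  quality, topicality, and phenotype specificity beyond the single
  `phenotype_realization` fraction are not represented.
* The medium- and high-functioning configurations differ mostly through
  evaluation accuracy; because both sit near the saturation of the
  selection-weight family, their separation in mean health is close to the
  smallest the architecture can resolve.
* Only closed cohorts are exercised by the reference experiments; the exit
  rules are provided for exploration and are deliberately simplistic.
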