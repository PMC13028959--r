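---
title: "Model and methods behind dapasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind dapasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dapasim)
```

## The problem

Dapagliflozin (DAP) is an SGLT2 inhibitor used in type 2 diabetes. It
lowers plasma glucose indirectly: by inhibiting sodium-glucose
co-transporter 2 in the proximal tubule it lowers the renal threshold for
glucose (RTG), so filtered glucose above the threshold escapes
reabsorption and appears in urine (urinary glucose excretion, UGE). The
drug is cleared mainly by UGT1A9 glucuronidation to
dapagliflozin-3-O-glucuronide (D3G), an inactive metabolite eliminated
renally; unchanged drug in urine is a minor route (<2% of dose).

`dapasim` implements a whole-body physiologically based
pharmacokinetic/pharmacodynamic (PBPK/PD) model of this system: mechanistic
organ-level disposition of DAP and D3G, coupled to a threshold model of
glucosuria, with scenario simulation, parameter scans over dose and
renal/hepatic/prandial state, non-compartmental analysis (NCA), local
sensitivity analysis, and multistart weighted least-squares calibration
against study-format datasets.

## Disposition model

The integrated state is a vector of compound amounts (µmol) in: gut lumen
(absorbable pool), fecal transit and cumulative feces, gut tissue, liver,
kidney, lung, rest-of-body, blood/plasma, cumulative urine (DAP); and
blood, kidney, cumulative urine (D3G). A lumped blood pool connects the
organs; each organ exchanges drug flow-limited with free-equivalent
venous concentration $C_T/K_p$:

$$\frac{dA_T}{dt} = Q_T\left(C_{bl} - \frac{C_T}{K_p}\right) + \text{local terms}.$$

Key structural choices, each of which was genuinely open:

* **Fractional volumes and flows.** FVgu 1.71%, FVki 0.44%, FVli 2.10%,
  FVlu 0.76% of body weight (1 kg/L); FQgu 18%, FQki 19%, FQh 21.5%
  (hepatic venous outflow; hepatic artery = 21.5% − 18% = 3.5% by
  conservation), FQlu 100% of cardiac output. Blood volume (7.86% of BW),
  cardiac output (108 L/h at 70 kg, linear in BW) and reference GFR
  (6.5 L/h at normal renal function) are not fixed by the sources the
  fractions come from; they are single named constants chosen at
  conventional resting values, and only relative flows matter for
  flow-limited distribution.
* **Partitioning.** A single partition coefficient Kp = 25.52 is applied
  to the named organs (gut, liver, kidney, lung). It is *not* applied to
  the rest-of-body compartment (Kp_re = 1): with Kp 25.52 on ~87% of body
  mass the steady-state volume of distribution would exceed 1700 L and no
  parameterization bounded by organ blood flows could reach a 13 h
  half-life; with Kp on the named organs only, Vss comes out near the
  drug's literature value (~120-170 L). D3G has no tissue partitioning
  (Kp_D3G = 1) and is restricted to blood plus kidney.
* **Rest-compartment exchange.** The rest of the body exchanges with
  plasma through a permeability-surface term `PS_re = ps_re * V_re`
  instead of its nominal blood flow. A flow-limited rest compartment
  equilibrates so fast that the plasma peak becomes
  distribution-controlled and nearly insensitive to the absorption rate,
  capping the fed-state Cmax reduction at ~25% — inconsistent with the
  30-50% fed effect the drug shows. `ps_re` is calibrated with the other
  disposition constants. The physiology object still reports
  FQre = 59.5% so that flow bookkeeping closes exactly.
* **Absorption.** First-order absorption (`ka`, scaled by the prandial
  factor `f_absorption`: 1.0 fasted, 0.3 fed, reflecting ~3-fold slower
  gastric emptying after a high-fat meal). The absorbable fraction of an
  oral dose is F_gut = 0.84; the remaining 16% is split off to the fecal
  route *at dosing time* and appears in cumulative feces with a slow
  first-order transit (0.05/h). The split-at-dose design makes the
  bioavailable fraction independent of absorption rate, matching the
  observation that food changes Cmax but not AUC; a competing-rates lumen
  model would not. Absorbed drug is routed into the portal/hepatic inflow
  stream (enterocyte transit treated as fast) rather than deposited in
  the Kp-partitioned gut tissue, which would add a spurious ~1.6 h
  absorption delay.
* **Metabolism.** Irreversible Michaelis-Menten conversion DAP → D3G in
  liver and kidney with a shared Km = 479 µM (kidney microsome value,
  fixed) and organ Vmax values `Vmax_li` (per L liver) and
  `Vmax_li * f_ki_Vmax` (per L kidney), driven by tissue concentration.
  Transport into hepatocytes and tubular cells is taken as fast and
  non-rate-limiting, so no explicit transporter states are carried.
* **Impairment scaling.** Renal function enters as `f_renal` (KDIGO-style
  classes: 1.00 / 0.69 / 0.32 / 0.19), multiplying GFR and both urinary
  excretion rate constants. Cirrhosis enters as `f_cirrhosis`
  (Child-Turcotte-Pugh A/B/C: 0.40 / 0.70 / 0.80), which both scales
  functional hepatic Vmax by `1 - f_cirrhosis` and diverts the same
  fraction of portal inflow past the liver as a portosystemic shunt.
* **Excretion.** First-order urinary excretion of DAP and D3G from the
  kidney amount (`k_DAPEX_ki`, `k_D3GEX_ki`, scaled by `f_renal`).

Mass is conserved exactly in DAP-equivalents: every state carries µmol of
drug skeleton, and the maximum relative balance error over any trajectory
is at integrator tolerance (<1e-12 in practice, tested against 1e-6).

## Pharmacodynamic model

The PD component is deliberately minimal. Total DAP plasma concentration
drives a saturable reduction of the renal threshold:

$$RTG(C) = RTG_0\left(1 - \frac{I_{max}\, C}{IC_{50} + C}\right), \qquad
UGE' = GFR \cdot f_{renal} \cdot \max(0,\ FPG - RTG),$$

with fasting plasma glucose (FPG) held constant per scenario (5 mM
healthy, 7.5 mM T1DM/T2DM by default, overridable per study). An
Emax-type form was chosen over a linear one because the UGE dose-response
saturates; tubular reabsorption capacity is represented implicitly by the
hard threshold rather than an explicit Tm-glucose curve, and diurnal
glucose excursions are not modelled. Because the PD has no feedback on
drug disposition, UGE is accumulated by trapezoidal quadrature of the
closed-form rate along the simulated plasma profile *after* integration
rather than as an ODE state. This makes the PK/PD decoupling structural:
plasma trajectories are bit-identical for any FPG, instead of merely
close to machine precision (an extra quadrature state would perturb the
adaptive step sequence).

## Reference parameterization

Six constants are not fixed by literature values: `ka`, `Vmax_li`,
`f_ki_Vmax`, `k_DAPEX_ki`, `k_D3GEX_ki`, `ps_re`. The shipped reference
set (`inst/extdata/reference_parameters.json`, regenerated by
`scripts/make_reference_parameters.R`) is calibrated so a single 10 mg
oral dose in the reference subject (75 kg, fasted, healthy) reproduces
the drug's headline behaviour: Tmax ≈ 3 h, terminal half-life 13 h,
absolute oral bioavailability 78%, unchanged drug in urine ≈ 1.3% of
dose, a fed-state Cmax reduction of ~38% (midpoint of the reported
30-50%), and a slightly delayed metabolite peak (~5 h). Two remarks on
identifiability: (i) with F_gut fixed at 0.84, a 78% bioavailability pins
hepatic extraction at ~7%, so most metabolic clearance is necessarily
renal glucuronidation — `f_ki_Vmax` comes out large; (ii) the
(`Vmax_li`, `f_ki_Vmax`) pair trades off along a flat valley constrained
only by first-pass loss and the D3G formation route, so the individual
values are less meaningful than their clearance combination.

PD reference values are RTG0 = 10 mM (upper healthy threshold band),
Imax = 0.90 and IC50 = 20 ng/mL, chosen to give a realistic glucosuria
magnitude (~45 g/24 h at 10 mg in a T2DM subject at FPG 7.5 mM) together
with the strong renal-function dependence and glucose dependence of UGE.

```{r}
str(reference_parameters()$drug)
```

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable, adaptive), rtol 1e-8 /
  atol 1e-10 for simulation; multi-dose regimens restart the integrator
  at every dose event, applied as instantaneous state increments.
  Reported Cmax/AUC move by <0.1% when tolerances are halved.
* The right-hand side exists twice by design: a compiled C version used
  by the solver, and an interpreted version generated from the same
  symbolic equation set (also the source of the SBML export). A test
  holds them to 1e-10 agreement.
* Fitting uses rtol 1e-6 with atol coupled at rtol/100.
* NCA: linear-up/log-down trapezoid; λz from log-linear regression over
  candidate windows of the last 3-10 points (Tmax excluded), best
  adjusted R² wins, ties to the larger window; AUC extrapolated by
  C_last/λz. Profiles with fewer than 3 positive declining terminal
  points flag AUC∞ as unavailable rather than guessing.
* Sensitivities: symmetric midpoint differences at ±1%, normalized to
  elasticities; entries with a zero reference parameter or zero baseline
  readout are NA (flagged, never silently 0). Rows below |S| < 0.1 are
  dropped before single-linkage clustering on Euclidean row distance
  (the linkage is the method's convention; the metric is the standard
  default and documented as a choice).
* Calibration: cost `F(p) = ½ Σ (n_k/σ_ik) r_ik²`; missing or zero SDs
  fall back to the series' median σ, and a series entirely without
  uncertainties gets σ = 10% of its median magnitude so
  differently-scaled observables (ng/mL plasma vs mg urine) contribute
  comparably. Starts are drawn log-uniformly inside physiologic bounds
  (e.g. ka ∈ [0.05, 10]/h) with a fixed seed; each start runs bounded
  Levenberg-Marquardt on log-parameters, and the best runs are polished
  by alternating Nelder-Mead and LM cycles because LM alone stalls on
  the flat hepatic/renal-Vmax valley. Residuals are on the linear
  concentration scale; simulation failures yield a large finite penalty.

## Synthetic study generator

`fixture_spec()`/`generate_study()` emulate the structure of curated
clinical datasets: per-arm dosing protocol and physiology, a sampling
grid, group size n, and per-point mean ± SD produced by drawing n
mean-preserving lognormal deviates per time point (default CV 20% for
plasma, 30% for urine/UGE — typical bioanalytical variability). A fixed
seed makes every dataset reproducible, and the generator restores the
caller's RNG state. `fixture_suite()` writes five canonical studies
(dose-ranging 2.5-500 mg, four-arm renal, four-arm hepatic, fed/fasted
crossover, 7-day multiple dose) with JSON sidecars recording the truth.

What the generator does *not* emulate — and therefore what passing
recovery tests do and do not show — matters: noise is multiplicative,
independent across time points and arms, with no inter-individual
physiological variability, no sparse/irregular sampling, no assay LLOQ
censoring, and the fitted model is exactly the generating model. Recovery
tests therefore validate the estimation machinery (cost, weighting,
multistart, bounds), not robustness to model misspecification on real
data.

## Problem sizes used by the shipped tests

The test suite and acceptance script run single- and multi-dose
simulations of 48-240 h at 0.1-0.5 h output resolution, parameter
recovery on two-arm fixtures (11 time points × 4 observables per arm)
with 20 multistarts noiseless and 10 with 10% noise, and a 300-replicate
Monte-Carlo check of the noise model. These sizes were chosen to exercise
every code path at full numerical fidelity while keeping the whole suite
near a minute of CPU.

## Known limitations

* The reference parameterization reproduces headline single-dose
  behaviour of a typical subject; it is not fitted to clinical
  time-course data, and no inter-individual variability is represented.
* The PD threshold model omits SGLT1, tubular Tm splay, diurnal glucose,
  insulin feedback and natriuresis; UGE predictions in poorly controlled
  diabetes are indicative only.
* D3G is the only metabolite; enterohepatic recirculation and intestinal
  glucuronidation are not modelled.
* Plasma protein binding is not resolved; the PD is driven by total
  plasma concentration.
* The flat SBML export encodes doses as initial amounts (t = 0 events
  only) and is validated structurally (well-formed L3V2, complete
  species/rules); no independent SBML simulator is bundled to cross-run
  it.
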