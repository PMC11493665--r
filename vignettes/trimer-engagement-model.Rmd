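---
title: "Modelling trimer formation by bispecific T-cell engagers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trimer formation by bispecific T-cell engagers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimerize)
```

## The model

T-cell engagers (TCEs) are bispecific antibodies with a low-affinity arm
for a T-cell receptor (TCR) co-receptor subunit and a high-affinity arm
for a tumour-associated antigen (TAA) on the target cell.  Efficacy is
driven by the ternary complex ("trimer") TCR–TCE–TAA that cross-bridges
effector and target cell.  `trimerize` implements the minimal well-mixed
mass-action model of this engagement: six species (free TCE, free TCR,
free TAA, the two binary complexes, the trimer) coupled by

* reversible binding of each arm, with both association routes to the
  trimer (via either dimer) and both dissociation routes out of it;
* zeroth-order synthesis and first-order degradation of each free
  receptor pool (`ksyn`, `kdeg`), so the drug-free fixed point of each
  pool is `ksyn/kdeg`;
* first-order internalization of drug-bound complexes (`kint`).

Canonical units are nM and seconds everywhere; converters at the boundary
(`receptors_to_concentration()`, `cell_context()`) translate cell counts
and receptor copy numbers into molar concentrations.

The central prediction is a bell-shaped (hook-effect) trimer
dose-response: at low exposure there is too little drug to bridge, at
high exposure each arm saturates separately and inactive dimers
outcompete the trimer.  Three qualitative laws describe how design
parameters displace the curve: higher antigen expression shifts it
upwards (without moving the optimal dose), higher antigen affinity shifts
it to the left, and higher TCR affinity shifts it upwards *and* to the
left.

## The parameter preset and its two dialects

`table1_preset()` ships a literature-derived baseline: micromolar TCR
affinity (Kd 1000 nM) at 1e5 receptor copies per T cell, nanomolar TAA
affinity (Kd 1 nM) at 1e4 copies per B cell, `kon` = 1e5 M⁻¹s⁻¹ for both
arms, receptor degradation `kdeg` = 1.834e-5 s⁻¹ and internalization of
bound receptor at 5.501e-5 s⁻¹ (trimer: 1.834e-5 s⁻¹).

The published table is internally inconsistent in two places: its
dissociation rates (0.26 s⁻¹ for TCR, 1.49e-3 s⁻¹ for TAA) do not equal
`Kd * kon` (0.1 s⁻¹ and 1e-4 s⁻¹), and its caption quotes an association
rate ten times the tabulated rows.  We do not silently repair this:
`table1_preset("as-printed")` (the default, used for figure
reproduction) keeps every rate verbatim and carries `consistent = FALSE`,
while `table1_preset("consistent")` re-derives `koff = Kd * kon`.  The
distinction matters quantitatively: equilibrium constants are governed by
`koff/kon`, so the as-printed dialect behaves like effective Kds of
~2600 nM (TCR) and ~14.9 nM (TAA) — its trace-limit optimum sits at
`sqrt(2600 * 14.9)` ≈ 197 nM rather than `sqrt(1000 * 1)` ≈ 31.6 nM.
Closed-form identities are therefore checked against the consistent
dialect.

Similarly, the tabulated synthesis rates are not reproducible from the
tabulated blood cell counts (the implied tissue is lymphoid, with no
density given): the preset's baseline pools are taken from the
`ksyn/kdeg` ratios (7.246 nM TCR, 0.04194 nM TAA), which is what actually
drives the ODE system, and the cell-count converter is provided for users
building explicit contexts (blood gives 0.339 and 0.0060 nM).

```{r preset}
table1_preset()
```

## Exposure modes and numerical choices

The free-TCE balance has no source or sink of its own, yet
internalization of complexes slowly drains total drug.  Two exposure
modes resolve this ambiguity:

* `"clamped"` (default for dose-response work): free TCE held constant,
  representing sustained local exposure.  This matches the steady-state
  reading of the dose-response figures, and is justified by
  pharmacokinetics: `exposure_decay()` shows a TCE with a 7-day
  half-life loses only ~9.4% of its concentration over 24 h, far slower
  than binding equilibration.
* `"free"`: the initial dose is a closed pool; useful for conservation
  checks and drug-depletion questions.

Integration uses a BDF method (`deSolve::vode`, mf = 21) with the
hand-derived analytic 6×6 Jacobian; the rate constants span about nine
orders of magnitude, so the system is treated as permanently stiff
(an auto-switching method can stall in its non-stiff phase near
equilibrium).  Default tolerances are `rtol = 1e-10`,
`atol = 1e-14` nM.  Negative concentrations are never clipped: any
reported value below `-atol` raises an error, since such excursions
indicate integrator misconfiguration rather than model behaviour.

## Steady states by two independent routes

`steady_state_algebraic()` solves the clamped-exposure balance equations
directly.  The complexes enter their own balances linearly, so for given
free receptor concentrations the dimers and trimer solve a 3×3 linear
system; substituting back leaves two nonlinear equations in the free
receptors, solved by damped Newton iteration on log-concentrations (the
log transform enforces positivity across ~6 orders of magnitude).  The
solver starts from the drug-free baseline and falls back to homotopy
continuation over a geometric dose ladder; mass-action binding networks
of this monomolecular form have a unique positive fixed point, and the
continuation guards against spurious roots.  Convergence is declared
only when the full-system residual max |dX/dt| falls below 1e-12 nM/s.

`steady_state_ode()` is the independent cross-check: clamped integration
from baseline, doubling the horizon from 48 h until the same residual
criterion is met.  The extension matters: receptor-pool turnover relaxes
on a `1/kdeg` ≈ 15 h timescale (slower still when `kdeg` is perturbed
downward), so a fixed 48 h horizon can sit a few tenths of a percent —
and at slow-turnover corners, tens of percent — away from the true fixed
point.  With the extension, the two routes agree to ~1e-6 % across a
100-point Latin hypercube within 4-fold of the preset (the acceptance
script measures this).

A receptor pool with neither turnover nor any internalization route is
*closed*; its turnover balance is degenerate and the solver switches that
pool's equation to conservation of the total at the baseline value.  This
is the classical ternary-complex equilibrium regime, used by the
closed-form checks below.

## Time to steady state: what "steady" means

A statement like "engagement equilibrates within 1–2 h" can only
describe the binding subsystem.  The full model keeps drifting long after binding
has equilibrated, because internalization of bound antigen (5.5e-5 s⁻¹)
outpaces basal degradation (1.8e-5 s⁻¹) and slowly re-sizes the antigen
pool — and the complexes inherit that drift.  Measured with a 5% stay-in
band against the 48 h terminal state, dimers and trimer settle only
after ~11–23 h at 1–100 nM doses, even though binding itself is done in
minutes.

`time_to_steady_state()` therefore offers three criteria and defaults to
the one that isolates binding:

* `"binding"` (default): turnover and internalization frozen at baseline
  pools; band-entry-and-stay of dimers and trimer.  Gives 0.1–0.5 h at
  1–100 nM with the preset, and reproduces the caveat that slow kinetics
  (`kon` < 1e4 M⁻¹s⁻¹) at sub-nanomolar exposure need many hours.
* `"complexes"`: full model, band on dimers and trimer (measures pool
  turnover, ~10–25 h).
* `"all"`: full model, band on every species except free TCE.

The 5% band is a convention (no standard numerical criterion exists for
"reached steady state"); it is exposed as `rel_tol`.

## Dose-response descriptors and shift classification

`sweep_dose_response()` computes equilibria over a log-spaced grid
(default 1e-3–1e6 nM, 61 points — the 1–100 nM clinical Cmax range with
three decades of margin on each side), warm-starting each solve from the
previous dose.  `describe_curve()` reduces a curve to:

* `peak_trimer` / `peak_dose`: grid argmax refined by quadratic
  interpolation in log-dose.  Without refinement the peak dose is
  quantized to the grid (a factor 1.41 at the default spacing), which
  would make horizontal-shift ratios useless.
* `plateau_low` / `plateau_high`: the dose interval where the trimer
  stays at or above 95% of peak (threshold exposed as
  `plateau_fraction`; the 95% convention is ours).
* `is_bell`: rise of ≥ 5% followed by fall of ≥ 5% with an interior
  maximum.

`compare_curves()` classifies the displacement of one curve against
another at threshold θ = 0.10 on the peak ratios; θ was chosen so that
2-fold parameter perturbations (the robustness study's range) do not
flip classifications, and is configurable.  The "up and to the left"
expectation for TCR affinity is checked jointly on the peak and on the
plateau-onset dose (`plateau_low_ratio`), since for an already-saturated
antigen arm the visible effect of more affinity is an earlier plateau.

Two closed-form limits anchor the descriptors:

* dilute closed pools: the trimer profile is proportional to
  `L / ((KdTCR + L)(KdTAA + L))`, peaking at `sqrt(KdTCR * KdTAA)`
  (31.6 nM for the consistent preset's 1000/1 nM);
* detailed balance (internalization off, turnover balanced): the
  equilibrium trimer equals `TCE·TCR·TAA / (KdTCR · KdTAA)` regardless
  of which association path dominates kinetically.

## The perturbation study

`run_perturbation_ensemble()` multiplies each of the 11 independent
parameters (`kon`, `Kd`, `kdeg`, the three `kint`, and the two baseline
pools) by an independent random factor in `[1/fold, fold]` and asks
whether the bell shape survives.  Dependent rates are never sampled:
`koff` scales with the `kd` and `kon` factors (preserving the base
dialect's `koff/(Kd·kon)` ratio, so a near-unity fold stays in a
neighbourhood of the base), and `ksyn = kdeg · baseline` exactly.

The factor distribution is log-uniform by default — "up to 2-fold" is a
scale statement, and log-uniform treats 0.5× and 2× symmetrically — with
linear-uniform available.  Each draw uses its own seed substream derived
from the master seed, so enlarging the ensemble reproduces the earlier
draws unchanged.  At 2-fold perturbation around the preset, all 200
default draws retain the bell shape (the acceptance script recomputes
this fraction).

## What the simulations do and do not show

All inputs are synthetic by construction — the model *is* the study
object, and the preset defines the study conditions.  The well-mixed
assumption replaces membrane-localized 2D binding between apposed cell
surfaces; 3D rate constants are a reasonable approximation for slow
binders (`kon` ≤ 1e6 M⁻¹s⁻¹) but the model says nothing about synapse
geometry, avidity, or clustering.  Trimer concentration is a proxy for
T-cell activation propensity, not a signalling model; no
cytokine-release, exhaustion, or tumour-kill layer is included, and no
biodistribution/PK layer couples exposure to dosing regimens
(`exposure_decay()` is a standalone utility).  Passing checks therefore
validate the engagement arithmetic and its qualitative design laws, not
clinical predictions.

Problem sizes used by the test and acceptance runs — 61–81-point dose
grids, a 100-point Latin hypercube, 200 perturbation draws, 20 random Kd
pairs — are the package's defaults for routine exploration; all scale up
linearly if finer resolution is wanted.

## Reproducing the standard figures

```{r figures, eval = FALSE}
# writes CSV artifacts and PNGs (requires ggplot2)
reproduce_figures("figures/")
```

Each figure is drawn from its exported CSV, never from in-memory state,
so any published curve can be regenerated from the artifact alone.
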