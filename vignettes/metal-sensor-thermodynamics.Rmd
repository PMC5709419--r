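---
title: "Coupled-equilibrium modelling of bacterial metal-sensor specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled-equilibrium modelling of bacterial metal-sensor specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalsens)
```

## The scientific problem

Metalloregulatory transcription factors are not chemically selective: the
relative affinities of a protein site for divalent metals follow the
Irving–Williams series, so a "zinc sensor" binds Zn(II) more tightly than
Co(II) simply because every protein does, and a "cobalt sensor" binds
Zn(II) *more* tightly than its own cognate metal. Selectivity in the cell
is therefore a systems property. This package implements the equilibrium
analysis that makes it quantitative: for each sensor, combine

* the combined metal affinity of the functional assembly, `1/K1`;
* the DNA affinities of the apo and metalated sensor, `1/K3` and `1/K4`;
* the number of sensor assemblies and DNA targets per cell;

into one coupled binding network, and ask at which *buffered* free-metal
concentration the sensor's promoter occupancy switches. Sensors are then
comparable on a single axis — the buffered concentration of a given metal —
and the cognate sensor should be the one with the lowest set point.

## The model

For one sensor, the network solved at every grid point is

* `P + M ⇌ PM` with association constant `K1`,
* `P + D ⇌ PD` with `K3`,
* `PM + D ⇌ PMD` with `K4`,
* `M + B ⇌ MB` with `K5`,

under mass balances for P, M, D and B. Metal binding to the `PD` state is
deliberately absent: its constant is fixed by thermodynamic-cycle closure
(`K1 K4 = K3 K2`), so adding it would add no information, and the
four-equilibrium network matches the published modelling script this
analysis mirrors. Occupancy is `(PD + PMD)/D_total`, except for the
MerR-family activator ZntR where the transcriptionally active species is
the metalated complex and the response is `PMD/D_total`.

Assumptions worth stating explicitly:

* **One effective metal-binding event per assembly.** The registry's metal
  affinities are "combined" constants across the assembly's sites (e.g.
  four Co(II) sites per Zur dimer showing no detectable cooperativity);
  the model does not resolve site-by-site filling. The known strong
  negative cooperativity of Zn(II) binding to Zur is likewise outside the
  model: the Zn(II) row uses the two tightest sites' combined constant.
* **One assembly per DNA molecule.** The 2:1 stoichiometries seen in
  anisotropy experiments live in the fitting module; the occupancy model
  treats `P + D ⇌ PD` directly, as the modelling script it reproduces
  does.
* **Equilibrium only.** No on/off rates, no transcription/translation
  dynamics; shock experiments are interpreted qualitatively against the
  equilibrium orderings.

## The buffer construction

The cytosolic pool of exchangeable ligands is abstracted as one species B.
Totals are fixed at `[M]_total = 0.01 M` and `[B]_total = 0.1 M` — metal
more than a thousandfold above total sensor, buffer tenfold above metal —
so free metal is set by the buffer alone to within the sensor sink
fraction, about `P_total/M_total ≈ 4e-6` relative. `K5` is not a measured
quantity; it is the *dial*: `k5_for_target()` inverts the two-component
equilibrium in closed form,

    K5 = (M_t − m) / ( m (B_t − M_t + m) ),

so any buffered concentration `m` in (0, M_t) can be realised exactly, and
`k5_sweep()` covers the fourteen decades 1e-3 … 1e-16 M. The package works
in molar association constants; the published script's constants are 100×
smaller (its worked example pairs an equilibrium constant of 1e-1 with
5.12e-3 M free metal at these totals, which forces 10 per molar), and
`script_keq_to_per_molar()` performs that conversion.

## Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| Cell volume | 1 fl | the volume used to convert copies/cell to molar |
| Temperature | 298.15 K | reproduces the reported coupling energies within ±0.05 kcal/mol; the source table does not state it, so this is an inference from numerical agreement, exposed as an argument |
| Metal grid | 61 log-spaced points, 1e-16–1e-3 M | resolves every set point to ~0.05 decade |
| `[M]_total`, `[B]_total` | 0.01, 0.1 M | the buffer construction above |
| Solver tolerance | 1e-12 relative | comfortably below the 1e-10 guarantee, at ~30 Newton iterations worst case |
| Titration noise | 1% relative Gaussian | replicate scatter is not quantified in the source experiments; 1% keeps recovery tests meaningful without being trivial |

DNA targets per cell are 1 (RcnR, ZntR), 4 (Zur, which has additional gene
targets) and 15 (FrmR/FrmR^E64H, carried on a low-copy reporter plasmid).

Bound-flagged affinities (apo-Zur's DNA Kd is a lower bound; the
metalated-RcnR DNA Kds likewise) are used as point estimates with the flag
carried through to reporting — this is the only reading that reproduces
the published coupling energies, and `run_reproduction()` logs every such
use in `parameter_substitutions`.

### Parameter-combination rules

`apply_modelling_rules()` converts the measured registry into the
modelling parameter set: where a sensor's Co(II) and Zn(II) DNA affinities
agree within error they are averaged (3.6e-8 M for Zur, 1.4e-5 M for
RcnR); the unmeasurable Co(II)-FrmR DNA affinity is estimated as
`Kd(Zn-FrmR) × Kd(Co-FrmR^E64H)/Kd(Zn-FrmR^E64H) ≈ 2.0e-6 M`. For ZntR the
reported average (4.7e-7 M) is not the mean of the reported per-metal
values (4.95e-7 M) — presumably it averages replicates that are not
reprinted — so the default keeps the per-metal values and both averaging
options are exposed rather than guessing which one the published curves
used.

## Numerical choices

**Speciation.** Concentrations in these networks span ~1e-16 to 1e-1 M, so
`solve_network()` iterates in log free-concentration space of the base
species, where the problem is well-scaled: a damped Newton iteration with
the analytic Jacobian `J_st = (δ_st f_s + Σ_c S_cs S_ct c_c)/T_s`, falling
back on per-coordinate bisection sweeps (each single-species mass balance
is monotone in its own free concentration) whenever a step fails to reduce
the residual. Zero totals and zero association constants are eliminated
analytically rather than special-cased numerically. The two-component
closed form computes *each free concentration from its own quadratic
branch* instead of `total − complex`; the subtraction form loses all
precision exactly where this model operates (free metal 1e-15 out of
0.01 M total). The test suite checks the solver against an independent
nested-root oracle and enforces mass-balance residuals below 1e-10
relative.

**Set points.** The response curves are drawn without any published
threshold, so the set point is defined here as the 0.5 crossing of the
[0,1]-normalised curve, interpolated linearly in log10 concentration. The
choice is arbitrary but order-preserving for monotone curves, which is
what the cross-sensor comparisons use. Normalisation is per-curve for set
points; the FrmR/FrmR^E64H pair is *additionally* normalised on a joint
scale (`frm_shared_scale` in the report), where FrmR^E64H's maximum stays
below FrmR's — on that shared scale its curve never reaches 0.5, which is
a feature of the biology (weaker apo-DNA binding), not a defect of the
model. Ranking flags sensors with set points less than twofold apart as
overlapping, since differences at that scale are not meaningful given the
input uncertainties.

**Titration fitting.** The forward models solve exact depletion equilibria
— these designs operate with probe and DNA totals far above the fitted
Kds, so no-depletion hyperbolas would be badly wrong. The signal is an
affine map of the designated complex concentration (the nuisance
parameterisation of the original fits is not printed; the affine map is
this package's choice, validated by round-trip recovery). Because the
nuisance parameters enter linearly they are profiled out exactly, leaving
a 1-D bounded least-squares problem in log10(Kd), multi-started from
probe-anchored points. Uncertainty comes from the local curvature of the
residual surface. Identifiability is checked rather than assumed: a fit
that lands at a bound, has non-positive curvature, or cannot beat the
protein-free null is flagged `converged = FALSE` with no Kd. The
magfura-2/RcnR design is packaged with exactly this behaviour in mind —
with the protein ~2000-fold tighter than the probe, the experiment bounds
the affinity but cannot measure it (noise-free data still round-trip, but
any realistic noise destroys the estimate), so it is excluded from the
quantitative recovery set.

## What the synthetic data do and do not show

The generators reproduce the *designs* of the source experiments (probe,
protein and DNA concentrations; stoichiometries; the fixed anisotropy
increment 0.025 per bound dimer) with seeded mean-zero Gaussian noise, and
the recovery tests show the fitting machinery is unbiased and precise
under those conditions: noise-free round trips to three significant
figures on every design, median log10 error below 0.18 at 1% noise over
20 seeds. They do not emulate baseline drift, pipetting error correlated
across points, inner-filter effects, or protein-stock mis-quantification —
so passing tests validate the estimators, not the systematic-error budget
of any real titration.

## Problem sizes

The shipped tests run the full two-metal, five-sensor reproduction on the
default 61-point grid, solver cross-checks on randomly parameterised three-
and four-species networks, and the 20-seed noise study for all seven
quantitative designs; the whole suite completes in about a minute on one
core. Larger grids change no ordering: set points move by less than 0.02
decades between 31- and 61-point grids.

## Known limitations

* Reported standard deviations on affinities are carried but not
  propagated into confidence bands on occupancy curves or set points.
* ZntR's ternary (two-dimer) DNA complexes at high concentrations are
  outside the 1:1 model; fits of that design truncate at 1500 nM monomer,
  mirroring the original analysis.
* The buffer is a single hypothetical ligand; no attempt is made to model
  glutathione or any chemically identified buffer component.
* In vivo transcript responses are compared qualitatively (orderings),
  never refit.
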