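---
title: "Implicit-solvent binding energetics of poly(gallic acid)–histidine complexes"
author: "polybind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implicit-solvent binding energetics of poly(gallic acid)-histidine complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polybind)
```

## The model

`polybind` analyses rigid-body complexes between an enzymatically derived
poly(gallic acid) oligomer (PGAL) and L-histidine, decomposing the binding
free energy per pose as

$$\Delta G_b \;=\; \Delta G_{solv} \;+\; \Delta G_{coul} \;+\;
\Delta G_{non\text{-}elec}.$$

* $\Delta G_{solv}$ — the change in electrostatic solvation free energy on
  binding, from a two-dielectric Poisson calculation: solvation energy of
  the complex minus those of the free receptor and ligand.
* $\Delta G_{coul}$ — the intermolecular Coulomb sum
  $\sum_{i \in R,\, j \in L} k_e\, q_i q_j / (\epsilon_{solute}\, r_{ij})$,
  evaluated in the uniform solute dielectric.  For rigid binding the
  intramolecular sums are unchanged and cancel, so only the cross term
  contributes.
* $\Delta G_{non\text{-}elec}$ — the hydrophobic term
  $\gamma\,\Delta SASA$, the solvent-accessible surface area buried on
  complex formation times an interfacial tension coefficient.

Histidine is treated in two protonation states.  The *protonated* species
carries an ammonium group, a carboxylate and a doubly protonated
imidazolium ring (net $+1$; both ring nitrogens are hydrogen-bond donors).
The *zwitterionic* species — the dominant form at physiological pH — has a
neutral imidazole (net $0$; the unprotonated ring nitrogen is an
acceptor).  The protonation state enters through the per-residue charge
templates and through the donor/acceptor roles used by the hydrogen-bond
map.

### Key parameters

| parameter | default | units | role |
|---|---|---|---|
| $\epsilon_{solvent}$ | 78 | — | water dielectric |
| $\epsilon_{solute}$ | 3.0 | — | polymer interior (polyimide-like) |
| probe radius | 1.4 | Å | water probe for SASA |
| $\gamma$ | 5 | cal mol$^{-1}$ Å$^{-2}$ | interfacial tension coefficient |
| H-bond cutoff | 3.35 | Å | heavy-atom donor–acceptor distance |
| ionic strength | 0 | mol/L | pure Poisson equation |
| temperature | 298.15 | K | reported with the constants |

The dielectrics, probe and $\gamma$ are the study conditions; grid spacing
and padding are numerical controls (below).  Zero ionic strength is the
minimal reading when no salt condition is stated, and it keeps the solver
analytically testable against the Born ion.

The Coulomb term is evaluated at $\epsilon_{solute} = 3.0$, the standard
choice in Poisson-based binding protocols when the solute interior defines
the charge environment.  Published component magnitudes alone cannot
distinguish this from an $\epsilon = 1$ convention; the choice is exposed
as the `eps` argument of `coulomb_energy()` so either convention can be
computed.

## What the synthetic structures are — and are not

The structural inputs of the original study (a quantum-chemically
optimized nonamer and its docked complexes) are not deposited, so the
package generates idealized stand-ins:

* a planar gallic-acid unit (carboxyl plus three ring hydroxyls, polar
  hydrogens explicit, nonpolar hydrogens folded into heavy-atom radii);
* a nine-unit oligomer stacked on a helical path (rise 3.6 Å, twist 36°
  per unit) — fixed idealized constants standing in for the unpublished
  helical geometry;
* histidine in the two protonation states sharing one heavy-atom skeleton;
* seeded rigid-body pose ensembles: uniform random orientations (Shoemake
  versor sampling) with the ligand slid along a random approach ray until
  its closest approach lands in the contact shell
  (`clash_min` 2.2 Å to `contact_max` 4.5 Å).  Fifty poses per replicate in
  triplicate mirror the study design; replicate $r$ uses seed $+\,r-1$.

Partial charges come from a bundled per-atom template table
(Gasteiger-like values normalized so each residue sums exactly to its
formal charge: 0 per gallic unit, $+1$ protonated histidine, 0
zwitterion).  The docking program named by the study does not define
partial charges, so no specific published charge set exists to reproduce;
the table is deliberately swappable (`read_charge_table()`), and every
quantitative test in the package depends only on formal-charge invariants
and closed-form oracles, not on particular template values.

Consequently, passing tests demonstrate that the *method* is implemented
correctly — the solver converges to analytic solvation energies, the
surface quadrature to analytic areas, the decomposition identity and sign
structure hold — not that the synthetic geometry reproduces the published
component energies (it cannot, and the package does not claim it).  The
published per-complex values are shipped as data
(`reported_energy_components()`) and re-enter only through the arithmetic
identity $\Delta G_b = \Delta G_{solv} + \Delta G_{coul} +
\Delta G_{non\text{-}elec}$.

## Numerical choices

**Poisson solver.**  Finite differences on a cubic-spacing grid;
seven-point stencil with harmonic averaging of the node dielectric on grid
edges; trilinear charge spreading; analytic Coulomb Dirichlet values on
the box faces; successive over-relaxation with
$\omega = 2/(1 + \sin(\pi/n_{max}))$, converged when the relative residual
drops below $10^{-6}$ (cap 20,000 sweeps — a non-converged solve is
flagged and refused downstream).  The dielectric boundary is the abrupt
van der Waals surface; no probe-traced cavity.  A two-level focusing pass
(4× coarser, widely padded box supplying fine-box boundary values) is used
for quantitative single-molecule work.

**Self-energy.**  The grid energy $\tfrac12\sum_i q_i \phi(r_i)$ contains
a large discretization self-energy.  It is removed strictly by
differencing two runs on the *identical* grid that differ only in the
exterior dielectric — never by analytic subtraction.  Grid origins snap to
multiples of the spacing, so a species at fixed coordinates has identical
node registration alone and inside a complex grid; this makes the
registration part of the self-energy cancel in
$\Delta G_{solv} = G_{complex} - G_{receptor} - G_{ligand}$ as well.  For
the same reason the free ligand's reference solvation is evaluated at the
*posed* coordinates (a rigid motion leaves the physical value unchanged,
but matching the registration removes the dominant numerical noise at
ensemble spacings).

At 0.25 Å focused spacing the solver reproduces the Born ion
($a = 2$ Å, $\epsilon\: 1 \to 78$, $-342.9$ kJ/mol) to under 2%, with
monotone error decay over grid levels (30% at 1 Å, 5% at 0.5 Å) — the
behaviour expected of a first-order-accurate abrupt dielectric boundary.

**Rigid-motion behaviour.**  Coulomb energies, distances and hydrogen
bonds are exactly invariant under rigid motion.  SASA uses a fixed global
golden-spiral point set (bit-reproducible), so it is exactly
translation-invariant and rotation-stable only to the quadrature
tolerance ($\sim$0.1% at 3840 points).  Finite-difference solvation is
exactly invariant under lattice-commensurate translations; under rotation
it varies by the discretization error of the grid level in use.  Tests
assert the exact invariances exactly and the discretization-limited ones
at their honest tolerances.

**Ensemble screening sizes.**  Default grid spacing is 0.5 Å.  Pose
ensembles (hundreds of Poisson solves) are screened at 1.0 Å spacing: at
that level individual solvation components carry a few kJ/mol of
discretization noise, which is acceptable for ranking synthetic rigid
poses and keeps a 50 × 3 × 2-state study around two minutes on one core.
The test suite and the reproduction script use these sizes.

**Hydrogen bonds.**  Heavy-atom donor–acceptor distance $\le$ 3.35 Å with
no angular term, since the templates carry polar hydrogens only.  This
follows the distance-based convention of interaction-map software; the
cutoff is a config field.  A pair bondable in both directions (two
hydroxyls) counts once.

**Pose scoring edge cases.**  Poses whose Poisson solve does not converge
are dropped from ranking with a logged reason, never imputed.  Ties in
$\Delta G_b$ break deterministically by (replicate, pose id).  Reports
round energies to two significant figures — the precision of the published
table — while objects retain full precision.

## Assay statistics

The probit dose–response model is $p = \Phi(\beta_0 + \beta_1 \log_{10}
c)$, fit by binomial maximum likelihood (`glm`, probit link) when
replicate counts are available and by least squares on fractions
otherwise; probit rather than logit because that is the named analysis,
with the logit available through standard `glm` if wanted.
$IC_{50} = 10^{-\beta_0/\beta_1}$, with a delta-method standard error.  An
estimate outside the observed response range is flagged as an
extrapolation rather than refused.  On noiseless synthetic curves with a
true $IC_{50}$ of 0.165 mg/mL (the published DPPH value for PGAL, used as
the generator truth) recovery is exact to well under 1%; under binomial
noise at 4 replicates per dose the median relative bias across 500
simulations stays below 5%.

Calibration curves are ordinary least squares with exact inversion for
quantification.  ROS inhibition is $100\,(control - treated)/control$
computed against the control of the same timepoint, reported rounded to
integers alongside full precision, with a >70% flag.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 17, n_poses = 50, replicates = 3, spacing = 1.0)
study <- run_binding_study(cfg)
study
cat(study$states$zwitterionic$report, sep = "\n")

# assay side
inhibition_table(ros_cellrox())
probit_ic50(simulate_dose_response(ic50 = 0.165, slope = 2.2))
```

## Known limitations

* The helical oligomer geometry is idealized; absolute component energies
  are not comparable to the published per-complex values, only the
  identity, signs and limits are.
* Rigid-body poses only: no torsional flexibility, no relaxation on
  binding, no scoring-function sampling bias.
* Abrupt dielectric boundary and linear, zero-salt Poisson equation; no
  probe-traced molecular surface, no nonlinear salt response.
* SASA counts polar hydrogens only, consistently across complex and free
  species; conventions that include all hydrogens will differ in absolute
  area but not in the tested identities.
* The probit fit on fractions without counts is least squares, not
  maximum likelihood; supply counts when they exist.
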