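# polybind

Implicit-solvent binding energetics for complexes of enzymatically derived
poly(gallic acid) (PGAL) with L-histidine, plus the accompanying
antioxidant-assay statistics.  The package is aimed at desk-scale
structural analyses: everything runs in minutes on one core from generated
structures, with no external electrostatics or docking executables.

## What it computes

For each rigid-body complex pose the binding free energy is decomposed as

    ΔG_b = ΔG_solv + ΔG_coul + ΔG_non-elec

* **ΔG_solv** — change in electrostatic solvation free energy on binding,
  from a finite-difference two-dielectric Poisson calculation
  (ε_solvent = 78, ε_solute = 3.0, zero salt), with self-energies removed
  by same-grid differencing.
* **ΔG_coul** — intermolecular Coulomb sum Σ k_e q_i q_j/(ε r_ij) in the
  solute dielectric.
* **ΔG_non-elec** — γ·ΔSASA with γ = 5 cal mol⁻¹ Å⁻² and Shrake–Rupley
  accessible surface areas (1.4 Å probe).

Poses are ranked by the most favorable ΔG_b and the best complex gets a
hydrogen-bond interaction map (heavy-atom donor–acceptor distance
≤ 3.35 Å).  Because the study's structures are not deposited, a
synthetic-structure module builds the inputs: an idealized helical
nine-unit PGAL oligomer, histidine in protonated (net +1) and
zwitterionic (net 0) states, and seeded rigid-body pose ensembles
(50 poses × 3 replicates per state) in a 2.2–4.5 Å contact shell.

The assay side implements probit IC50 estimation
(p = Φ(β₀ + β₁ log₁₀ c), IC50 = 10^(−β₀/β₁) with delta-method SE), linear
calibration curves with inversion, and control-relative ROS-inhibition
percentages, with the published positive-cell table bundled as data.

## Worked example

```r
library(polybind)
cfg <- run_config(seed = 17, n_poses = 10, replicates = 3, spacing = 1.0)
study <- run_binding_study(cfg)
study
#> <binding_study>
#>   protonated    30 poses scored, best dG_b    -3.49 kJ/mol
#>   zwitterionic  30 poses scored, best dG_b    -3.54 kJ/mol
#>   note: zwitterionic best pose binds at least as favorably as protonated

cat(study$states$zwitterionic$report, sep = "\n")
#> == interaction report: PGAL-zwitterionic histidine ==
#> pose 1 (replicate 1)
#>
#> dG_solv          6.9 kJ/mol
#> dG_coul         -6.9 kJ/mol
#> dG_non-elec     -3.5 kJ/mol
#> dG_b            -3.5 kJ/mol
#>
#> hydrogen bonds (heavy-atom cutoff): 1
#>   GAL4:O5          HID1:NE2           3.26 A
```

The decomposition shows the expected physics of a polar contact: an
unfavorable desolvation penalty (ΔG_solv > 0) opposing a favorable Coulomb
term of nearly equal magnitude (solvent screening), with the buried-area
term tipping the balance.  Synthetic geometries reproduce the method, not
the published absolute energies; the published component table is bundled
(`reported_energy_components()`) and its row sums are what the
decomposition identity reproduces exactly (−55 and −88 kJ/mol).

```r
head(inhibition_table(ros_cellrox()), 4)
#>      treatment timepoint percent_positive inhibition_rounded flagged
#> 1     PGAL 100        24            33.40                 46   FALSE
#> 2     PGAL 200        24            22.82                 63   FALSE
#> 3 PGAL-His 133        24            33.32                 46   FALSE
#> 4 PGAL-His 266        24            26.31                 58   FALSE

probit_ic50(simulate_dose_response(ic50 = 0.165, slope = 2.2))
#> IC50 = 0.165 +/- 2.7e-17 (probit slope 2.2)
```

A thin command-line wrapper with `generate`, `score`, `rank`, `report`,
`ic50`, `calibrate` and `inhibition` subcommands lives at
`inst/cli/polybind.R` (installed under `system.file("cli", "polybind.R",
package = "polybind")`).

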