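---
title: "Predicting pyrolysis activation enthalpies from reactant electron-density descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pyrolysis activation enthalpies from reactant electron-density descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eplbarriers)
```

## The problem and the model

Hemicellulose pyrolysis proceeds through a small set of recurring elementary
steps of the xylan building block, beta-D-xylopyranose, and its acetylated,
methoxylated and carboxylated variants: **ring-opening** to the acyclic
sugar, **ring contraction** to furanics, and **elimination** of water,
acetic acid or methanol to anhydro sugars. Screening these networks with
transition-state searches is expensive; `eplbarriers` implements an
Evans-Polanyi-like (EPL) shortcut in which the reaction enthalpy of the
classic Evans-Polanyi relation is replaced by three electron-density
reactivity descriptors computed **from the reactant alone**:

$$\Delta H^{\ddagger} \;=\; c_f\,\bar f \;+\; c_N\,\bar N \;+\;
  c_g\,\overline{\Delta g}^{\mathrm{pair}} \;+\; c_0$$

* $\bar f$ — mean of condensed Fukui functions over the reacting centers
  ($f^0$ on carbons, $f^-$ on oxygens; dimensionless);
* $\bar N$ — mean electron population of the ELF disynaptic basins of the
  breaking C–O (and C–C) bonds (electrons);
* $\overline{\Delta g}^{\mathrm{pair}}$ — mean gross (unnormalized) IGM
  pair bond-strength index over the breaking/forming pairs (dimensionless).

Four published coefficient sets are packaged (`epl_model()`), one per
reference level of theory (DFT = M06-2X/6-311++G(d,p), CBS-QB3, G4 and
DLPNO-CCSD(T)-F12), all in kcal/mol at 298 K. Fitting new coefficient sets
from user data is `fit_epl()`; the packaged constants are never
overwritten by a refit.

## Descriptor pipeline

All three descriptors are functionals of the reactant electron density on a
uniform volumetric grid. Densities enter either from analytic Gaussian
orbital models (`orbital_model()`, used by the test fixtures) or from any
quantum-chemistry package via Gaussian cube files (`read_cube()`).

**Condensed Fukui functions** use vertical finite differences of Hirshfeld
populations over three charge states at a fixed geometry:
$f^+_A = N^A_{N_0+1} - N^A_{N_0}$, $f^-_A = N^A_{N_0} - N^A_{N_0-1}$,
$f^0_A = (f^+_A + f^-_A)/2$. The radical index is implemented as the
standard half-sum of $f^+$ and $f^-$ (equivalently the half-difference of
anion and cation populations); a bare half-sum of the state *densities*
appears in parts of the literature but is dimensionally inconsistent with a
density response, so the standard convention is used and documented rather
than switched silently. Hirshfeld weights come from packaged
single-exponential free-atom densities $\rho_Z(r) = Z\zeta^3/(8\pi)
e^{-\zeta r}$ — crude radial models, but the weights depend only on density
*ratios*, for which they are adequate. Negative condensed values are
retained, never clipped.

**ELF basin populations.** The electron localization function
$\eta = 1/(1+(\tau_P/\tau_H)^2) \in [0,1]$ is built from the
positive-definite Pauli kinetic energy density and the Thomas-Fermi
reference. Basins are found by a discrete steepest-ascent watershed:
every voxel follows its highest neighbor (26-connectivity) to a local
maximum. Numerical choices, all surfaced as arguments:

* density floor `rho_min = 1e-6` e/bohr^3 — below it the defining ratio of
  ELF degenerates to 0/0, so such voxels are excluded (label −1);
* $\tau_P < 0$ from finite precision is clamped to zero;
* ascent ties are resolved lexicographically: strictly higher $\eta$ wins,
  exact $\eta$ ties fall back to higher density, and full ties chain to the
  lowest flat index. The density tie-break matters for closed-shell
  single-orbital models, whose ELF is *identically* 1 wherever defined —
  the density then supplies the topography, and the partition remains
  deterministic;
* grid maxima closer than `merge_radius = 0.3` bohr are fused (one
  physical attractor fragments at finite spacing);
* synaptic classification (the literature names the concept but no
  algorithm): attractors within 0.35 bohr of a nucleus with Z > 2 are core
  basins; valence basins connect to every atom whose free-atom density
  exceeds 5% of the promolecule density at the attractor — exactly two
  atoms makes the basin disynaptic V(A,B).

Populations are masked density integrals, so the closure
$\sum_\Omega N + \text{residue} = \int\rho$ holds to machine precision by
construction; $\int\rho = N_0$ holds within grid tolerance (about $10^{-2}$
electrons at 0.2 bohr spacing for the fixture models).

**Gross IGM pair index.** For a pair (A, B),
$\delta g^{\mathrm{pair}} = |\nabla\rho_A| + |\nabla\rho_B| -
|\nabla\rho_A + \nabla\rho_B| \ge 0$, with atomic densities
$\rho_A = w_A \rho$ (Hirshfeld partition of the *actual* density; a
promolecular variant is available). Two deliberate conventions: the index
is **unnormalized** — no division by $d_{AB}^2$ and no reference-molecule
scaling (the distance is stored for bookkeeping only) — and the
integration domain is the **whole grid**, since $\delta g^{\mathrm{pair}}$
has compact support in the interatomic region; an isosurface cutoff would
introduce an arbitrary boundary for no gain. Atomic-density gradients are
taken by central differences on the grid (the weight-times-density product
rule is absorbed into the discrete stencil).

## Reaction-class recipes

`build_recipe()` emits the exact site/bond/pair label lists per class —
ring-opening (3 Fukui sites, 1 bond, 2 pairs), two ring-contraction
channels (5 sites; 1 or 2 bonds; 3 pairs) and eliminations at positions
1–7 (3 sites, 1 bond, 2 pairs) — using the pyranose ring numbering
convention: ring carbons C1–C5 (C1 anomeric), ring oxygen O, hydroxyl
oxygens O1–O4 numbered by their carbon, protons H_Oi and Hi. When a recipe
consumes a substituted position, the proton-transfer pair Oi–H_Oi is
relabeled to the actual leaving-group linkage (e.g. O2–Cac2 for a 2-O-acetyl
group) with a warning — ambiguities are surfaced, never resolved silently.
`aggregate_descriptors()` then averages the tabulated values
(`descriptor_table()`) into $(\bar f, \bar N,
\overline{\Delta g}^{\mathrm{pair}})$.

An optional `fukui_cache()` implements the screening refinement of keeping
parent-sugar Fukui values frozen at unsubstituted sites and recomputing
only functionalized ones; it is opt-in and logs every reuse.

## Grids and numerics

The default grid (`default_grid()`) uses 0.2 bohr spacing and a 5 bohr
margin beyond the molecular bounding box; integration is a midpoint
Riemann sum with constant voxel weight. Descriptor values are
grid-converged plateaus, not high-precision quadratures — the test suite
checks 2% stability under refinement to 0.15 bohr, and tighter adaptive
quadrature would buy nothing at the modeling accuracy of an EPL relation.
Positions are bohr internally; cube files follow the standard dialect
(third index fastest). Non-orthogonal grid axes are accepted on input and
flagged; numerical gradients require orthogonal axes.

## Level extrapolation

Two independent tools close the gap between cheap and accurate barriers:

* `level_map()` / `apply_level_map()` — six packaged affine maps between
  barrier levels (DFT→CBS, DFT→G4, DFT→DLPNO, CBS→G4, CBS→DLPNO,
  G4→DLPNO), fit anew from paired barriers with `fit_level_map()`. Whether
  such maps should pool 0 K and 298 K barriers is a user choice:
  `fit_level_map()` fits whatever pairs it is given and labels the result.
* `cbs_extrapolate()` — two-point complete-basis-set extrapolation with an
  exponential SCF channel ($\alpha = 4.42$) and an inverse-power
  correlation channel ($\beta = 2.46$), packaged for the (2, 3) cardinal
  pair; energies are unit-agnostic pass-through.

## What the synthetic fixtures emulate — and what they do not

The package cannot ship wavefunctions, so tests run on two kinds of
synthetic input, both first-class code:

* **Analytic toy densities** (`toy_density_suite()`): four closed-shell
  s/p-Gaussian models (one-center, homonuclear sigma, polar cation, bent
  ten-electron) with cation/anion variants at fixed geometry. Orbitals are
  Gram–Schmidt orthonormalized with *analytic* overlaps, so each state's
  density integrates exactly to its electron count and the Fukui sum rules
  are meaningful grid checks. Exponents are kept soft (max ~8 bohr^-2) so
  a 0.2 bohr grid resolves every feature; real core densities are far
  sharper, which is one reason real systems should enter via cube files on
  grids matched to their hardest feature. The toys probe the *mechanics*
  (closure, symmetry, sum rules, monotonicity), not chemical realism:
  passing them says the descriptor plumbing is correct, not that the toy
  values resemble sugar chemistry.
* **Synthetic regression rows** (`synthetic_regression_dataset()`):
  descriptors uniform over ranges bracketing plausible magnitudes
  ($\bar f \in [0.02, 0.12]$, $\bar N \in [0.8, 1.8]$,
  $\overline{\Delta g} \in [0.2, 1.2]$) with barriers from known
  coefficients plus Gaussian noise. The fitting pipeline is validated by
  parameter recovery — exact at zero noise, within three standard errors
  at 1 kcal/mol noise — because the full descriptor/barrier dataset behind
  the published coefficients is not distributable; consequently the
  published regression-quality statistics are quoted as packaged context,
  not re-derived here.

Test problem sizes (default grids of the toy models, up to roughly
2·10^5 voxels; 100-replicate regression recovery at n = 200) were chosen as
the smallest sizes at which every property above is comfortably inside its
tolerance.

## Known limitations

* No electronic-structure solver: densities must come from cube files or
  the analytic fixture models (s/p Gaussians only; no wfn/wfx/molden).
* Basin attractors live on grid points; no continuous refinement of
  attractor positions is attempted (the watershed populations are stable
  well within the 2% refinement tolerance the tests enforce).
* The species builder is composition-and-labels bookkeeping — substituent
  arithmetic, electron counts, dimer condensation — not a conformer
  generator; 3D structures of the real sugars are deliberately out of
  scope.
* Free-atom models cover Z ≤ 18, comfortably including C/H/O chemistry.

## A worked micro-example

```{r example}
# descriptor table for a hypothetical reactant
tab <- descriptor_table()
tab <- add_fukui_rows(tab, "demo", c("C1", "O", "O1"),
                      data.frame(f_plus = c(0.10, 0.05, 0.04),
                                 f_minus = c(0.06, 0.09, 0.08),
                                 f_zero = c(0.08, 0.07, 0.06)))
tab <- add_bond_rows(tab, "demo", "V(C1,O)", 1.23)
tab <- add_pair_rows(tab, "demo", c("C1-O", "O1-H_O1"), c(0.62, 0.49))

rec <- build_recipe("ring_opening")
agg <- aggregate_descriptors(rec, tab, "demo")
agg

dft <- predict_barrier(epl_model("DFT"), agg)
dft
apply_level_map(level_map("DFT", "G4"), dft)
```
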