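# eplbarriers

Evans–Polanyi-like (EPL) prediction of standard activation enthalpies for
the elementary reactions that govern hemicellulose (xylan) pyrolysis —
ring-opening, ring contraction and elimination of functionalized
β-D-xylopyranoses — from electron-density reactivity descriptors computed
**for the reactant only**. The package is aimed at kinetic modelers who
need to triage large pyrolysis reaction networks without running a
transition-state search for every step.

## The model

The classic Evans–Polanyi relation maps a reaction enthalpy to an
activation energy. Here the thermodynamic driving force is replaced by
three reactant descriptors:

    ΔH‡ = c_f·f̄ + c_N·N̄ + c_g·Δḡᵖᵃⁱʳ + c₀        [kcal/mol, 298 K]

* **f̄** — mean condensed Fukui function over the reacting centers
  (Hirshfeld-condensed; f⁰ on carbons, f⁻ on oxygens),
* **N̄** — mean electron population of the ELF disynaptic basins of the
  breaking bonds (grid-watershed basin integration),
* **Δḡᵖᵃⁱʳ** — mean gross (unnormalized) independent-gradient-model pair
  bond-strength index over the breaking/forming atom pairs.

Four published coefficient sets are packaged (`epl_model("DFT" | "CBS" |
"G4" | "DLPNO")`), along with six affine level-of-theory extrapolation
maps (`level_map()`) and a two-point complete-basis-set extrapolator
(`cbs_extrapolate()`, α = 4.42 / β = 2.46 for the (2,3) cardinal pair).
The full volumetric stack — Gaussian cube I/O, analytic Gaussian-orbital
model densities, ELF fields and basin populations, Hirshfeld/Fukui
condensation, IGM pair fields — is exposed so descriptors can be computed
from any quantum-chemistry package's cube exports.

## Worked example

Aggregate a descriptor table through the ring-opening recipe and predict
the barrier at two levels:

```r
library(eplbarriers)

tab <- descriptor_table()
tab <- add_fukui_rows(tab, "demo", c("C1", "O", "O1"),
                      data.frame(f_plus = c(0.10, 0.05, 0.04),
                                 f_minus = c(0.06, 0.09, 0.08),
                                 f_zero = c(0.08, 0.07, 0.06)))
tab <- add_bond_rows(tab, "demo", "V(C1,O)", 1.23)
tab <- add_pair_rows(tab, "demo", c("C1-O", "O1-H_O1"), c(0.62, 0.49))

agg <- aggregate_descriptors(build_recipe("ring_opening"), tab, "demo")
agg
#> f_bar = 0.0833, n_bar = 1.2300 e, g_bar = 0.5550

predict_barrier(epl_model("DFT"), agg)
#> [1] 67.7028
apply_level_map(level_map("DFT", "G4"), 67.7028)
#> [1] 66.7147
```

The first number is the predicted standard activation enthalpy (kcal/mol,
298 K) at the DFT reference level; the second extrapolates it to the G4
level through the packaged affine map. The packaged benchmark table of 30
reactions × 5 theory levels × 2 temperatures is available through
`load_table1()`; e.g. `table1_barrier("xylose", "DXP", "DFT", 298)`
returns `45.54`.

A command-line front end covering the whole workflow (cube files →
descriptor table → aggregation → prediction, plus fitting, level maps and
CBS extrapolation) ships as `inst/scripts/eplbarriers-cli.R`; see
`?run_cli`.

## Package layout

* `R/` — grids, cube I/O and analytic fields; ELF and basin integration;
  Hirshfeld/Fukui; IGM pair index; recipes and descriptor tables; EPL
  fitting (`fit_epl()` returns a classed model with `print`/`coef`/
  `predict`/`residuals`/`plot` methods); level and CBS extrapolation;
  fixtures; CLI.
* `inst/extdata/` — the packaged barrier table (plain TSV + JSON schema).
* `vignettes/epl-barrier-prediction.Rmd` — the methods vignette: model
  assumptions, numerical choices, fixture design and limitations.
* `tests/testthat/` — unit and property suites, including end-to-end
  acceptance properties.
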