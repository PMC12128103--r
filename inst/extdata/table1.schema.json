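{
  "description": "Activation enthalpies (kcal/mol) at 0 and 298 K for ring-opening, ring contraction and elimination reactions of xylose, 2-O-acetyl-xylose and 4-O-methyl-D-glucuronic acid at five levels of theory. Wide format; '-' marks barriers that could not be located (transition-state search failure).",
  "columns": {
    "reactant": "reactant species id",
    "product": "product label (DXP, FF1/FF2, AXP1-7, OADXP, FFL1/FFL2, AXPL1-7, DGLA)",
    "leaving": "leaving molecule: H2O, CH3COOH, CH3OH or none",
    "class": "reaction class: ring_opening, ring_contraction, elimination",
    "dft_0": "dH at M06-2X/6-311++G(d,p), 0 K",
    "cbs_0": "dH at CBS-QB3, 0 K",
    "g4_0": "dH at G4, 0 K",
    "dlpno_0": "dH at DLPNO-CCSD(T)-F12/cc-pVTZ-F12, 0 K",
    "dlpnocbs_0": "dH at DLPNO with two-point CBS extrapolation, 0 K",
    "dft_298": "as dft_0 at 298 K",
    "cbs_298": "as cbs_0 at 298 K",
    "g4_298": "as g4_0 at 298 K",
    "dlpno_298": "as dlpno_0 at 298 K",
    "dlpnocbs_298": "as dlpnocbs_0 at 298 K",
    "relaxed": "semicolon-separated list of value columns obtained under relaxed convergence criteria (excluded from benchmarking analyses)"
  },
  "units": "kcal/mol",
  "missing": "-"
}
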