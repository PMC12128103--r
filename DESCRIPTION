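Package: eplbarriers
Title: Evans-Polanyi-Like Prediction of Pyrolysis Activation Enthalpies
    from Reactant Electron-Density Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts standard activation enthalpies of the three reaction
    classes governing hemicellulose (xylan) pyrolysis -- ring-opening, ring
    contraction and elimination of functionalized beta-D-xylopyranoses --
    from reactant-only electron-density reactivity descriptors via
    Evans-Polanyi-like (EPL) linear models. Provides volumetric scalar-field
    infrastructure with Gaussian cube input/output, electron localization
    function (ELF) evaluation and grid-watershed basin integration,
    Hirshfeld-condensed Fukui functions, the unnormalized independent
    gradient model (IGM) pair bond-strength index, reaction-class descriptor
    aggregation recipes, multilinear EPL fitting and evaluation, packaged
    published coefficient sets, level-of-theory linear extrapolation maps
    and two-point complete-basis-set (CBS) extrapolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
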