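Package: hpbrush
Title: Coarse-Grained Simulation of Globular Protein Adsorption on Polymer Brushes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained coarse-grained molecular dynamics toolkit for
    studying the adsorption of hydrophobic-polar (HP) model globular proteins
    on bead-spring polymer coatings tethered to implicit 9-3 walls. Builds
    complete particle systems (tethered coatings at prescribed grafting
    density, randomly sequenced HP proteins, explicit coarse-grained water,
    attractive backbone/terminal/ligand doping), integrates them under NVT or
    NVE conditions with Nose-Hoover or Langevin thermostats, and analyses the
    results: chain and protein conformational metrics, adsorbed fractions,
    z-density profiles, gyration-tensor asphericity, and potential-of-mean-force
    estimation by umbrella sampling with a weighted histogram analysis method
    (WHAM) solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
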