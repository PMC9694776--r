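Package: mixjdp4
Title: Stereochemical Assignment from NMR Data with DP4, J-DP4 and
    mix-J-DP4 Probabilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for NMR-based assignment of relative configuration in
    small organic molecules. Curates force-field conformer ensembles
    (energy-window filtering, Kabsch superposition, MAD/RMSD redundancy
    elimination), assembles Boltzmann-averaged isotropic shieldings into
    referenced and linearly scaled chemical shifts, and ranks candidate
    stereoisomers with Student-t Bayesian probabilities: DP4 from 1H/13C
    shift errors, dJ-DP4 adding a 3JHH coupling channel, iJ-DP4 filtering
    conformers through a Karplus dihedral window, their combination
    iJ/dJ-DP4, and mix-J-DP4, which averages iJ/dJ-DP4 probabilities
    obtained from several independent force-field ensembles. Includes a
    fully ground-truthed synthetic data generator and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    bio3d,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
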