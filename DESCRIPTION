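Package: dhaspec
Title: Composite Double-Harmonic Infrared Spectra and Spectral Benchmarking
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for gas-phase infrared spectra in the double-harmonic
    approximation with freely combinable ingredient methods: seminumerical
    Hessians and normal-mode analysis from any gradient provider, numerical
    dipole-moment derivatives from any dipole provider, double-harmonic
    intensities in km/mol, Lorentzian line broadening, zero-point
    vibrational energy (ZPVE) based linear frequency scaling, spectral
    similarity scores (Cauchy-Schwarz matchscore, Euclidean, Pearson,
    Spearman), method-combination score matrices, and the benchmark
    statistics used to compare low-cost electronic-structure methods
    (regularized dipole errors, dipole alignment, Kabsch RMSD, MD/MAE/RMSE/SD
    summaries, threshold fractions, log-normal fits). Includes analytic toy
    models (harmonic force field, point-charge dipoles) that serve as exact
    oracles, plus plain-text readers and writers for XYZ geometries, Hessians,
    dipole derivatives, and spectra, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
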