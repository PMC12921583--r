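Package: levitrap
Title: Spectral Analysis and Classification of Levitated Nanoparticle Motion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the centre-of-mass motion of optically
    levitated silica nanoparticles and for detecting surface
    functionalization (e.g. adsorbed oligonucleotides) from it. Provides a
    Langevin simulator of the damped thermal harmonic oscillator with an
    exact discrete-time update, Welch power spectral density estimation,
    Lorentzian peak fitting with equipartition-based detector calibration,
    kinetic-regime (Epstein) gas-damping radius and mass estimation,
    interquartile-range outlier filtering of per-particle feature tables,
    supervised UMAP embedding, random-forest classification under Monte
    Carlo cross-validation, and a core-shell polarizability model of the
    trap-frequency shift caused by a molecular coating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    pracma,
    randomForest,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
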