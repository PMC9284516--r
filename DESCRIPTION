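Package: oligodeer
Title: DEER Distance Analysis and Ensemble Statistics for Cu(II)-Labelled
    Amyloid Oligomers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain linking pulsed double electron-electron resonance
    (DEER) measurements of Cu(II)-labelled amyloid-beta oligomers to structural
    ensemble models. Provides a forward model of the four-pulse DEER dipolar
    evolution signal, exponential background correction, Tikhonov inversion
    with non-negativity to recover interspin distance distributions, L-curve
    regularization-parameter selection, a synthetic generator of coarse-grained
    tetramer ensembles with controllable Cu-Cu distance laws and
    coordination-plane alignment, pair-class distance and orientation
    statistics, Shrake-Rupley solvent-accessible surface area with a
    SASA-ratio tetramer filter, rank-based sample comparison, and
    representative-configuration selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
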