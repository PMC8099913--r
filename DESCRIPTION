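Package: DSFbinding
Title: Binding Affinities from Differential Scanning Fluorimetry Melting Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies protein-ligand dissociation constants from thermal
    unfolding curves measured by label-free differential scanning fluorimetry
    (nDSF). Implements a reversible two-state unfolding model coupled to 1:1
    ligand binding: local (per-curve) and global (shared-parameter) nonlinear
    least-squares fitting of melting curves, optional global fitting of the
    heat-capacity change upon unfolding, isothermal extraction of Kd from
    fraction-unfolded dose-response data with temperature selection by minimal
    fitting error, melting-temperature-shift models for apparent affinities,
    and a virtual binding-study simulator with a Kd-recovery benchmark.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), methods, SummarizedExperiment
Imports: stats, utils, graphics, grDevices, tools, jsonlite, S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
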