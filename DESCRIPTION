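Package: fluctnet
Title: Compressibility from Number Fluctuations and Hydrogen-Bond Network
    Analysis for Molecular Liquids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-liquid trajectories with cubic
    periodic boxes: oxygen-oxygen radial distribution functions, the static
    structure factor on the reciprocal lattice (direct sum and Fourier
    transform of g(r)), the isothermal compressibility from the k->0 limit of
    S(k), spatial block analysis (SBA) of subvolume number fluctuations with
    finite-size extrapolation, the NPT volume-fluctuation estimator, and
    geometric hydrogen-bond detection with cluster and modularity statistics
    of the resulting network. Includes synthetic-trajectory generators with
    recorded ground truth (binomial gas, clustered fluid, planted hydrogen-bond
    chains, planted-partition graphs) so every estimator is testable without
    molecular-dynamics input, plus native GRO and extended-XYZ readers and a
    temperature-series driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
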