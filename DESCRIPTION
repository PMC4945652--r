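Package: lfpcsd
Title: Forward Modeling of LFP and CSD Phase-Patterns on Multi-Electrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates parametric three-dimensional oscillatory current source
    densities (CSDs), computes the local field potentials (LFPs) they generate
    on an intracortical multi-electrode grid through a homogeneous
    volume-conductor model with an exact analytic cuboid-source leadfield, and
    quantifies discrepancies between LFP and CSD phase-patterns. Provides the
    Kuramoto order parameter, phase-gradient propagation-speed estimation,
    LFP-CSD phase-coherence, the two-source phase-contraction check, and
    re-referencing montages (referential, average-reference, bipolar, surface
    Laplacian), together with seeded experiment drivers for phase-coherence,
    propagation-speed, laminar-phase, and montage-comparison studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
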