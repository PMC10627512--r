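Package: saxsrb
Title: Small-Angle X-Ray Scattering Analysis and Restrained Rigid-Body
    Refinement for Partially Oligomerizing Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing solution small-angle X-ray scattering
    (SAXS) data from multi-chain protein complexes that partially
    oligomerize in solution.  Implements model-free primary analysis
    (Guinier fit, molar mass from forward scattering, indirect Fourier
    transform to the pair distance distribution p(r), normalized Kratky
    transform), a Debye-equation forward model with an average-atom
    coarse-graining and a hydration dummy-atom shell, a two-parameter
    oligomerization structure factor applied in the decoupling
    approximation, and restrained, C2-symmetric rigid-body refinement by
    multi-start simulated annealing with simultaneous refinement of the
    oligomer parameters.  Also provides a synthetic-data generator for
    end-to-end recovery testing and a small classifier for Ser/Thr kinase
    Gly-rich-loop phosphosite motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
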