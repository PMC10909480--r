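Package: HistoMech
Title: Computational Homogenization of Glandular Tissue Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Histology-based computational homogenization of glandular soft
    tissue. From a segmented three-phase microstructure (stroma, epithelial
    compartment, acinar lumen) the package estimates apparent anisotropic,
    tension-compression-asymmetric elastic moduli by plane-stress finite
    element homogenization with periodic boundary conditions, using
    Holzapfel-Gasser-Ogden fibre-reinforced hyperelasticity for the stroma
    and neo-Hookean models for the other constituents. Includes
    mean-intercept-length fabric tensor analysis with degree of anisotropy,
    structure-tensor fibre orientation mapping, a seeded generator of
    synthetic three-phase microstructures, orthotropic mirror construction of
    periodic representative volume elements, and drivers for parametric
    sweeps, benchmarking and area-fraction correlation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'constitutive.R'
    'fabric.R'
    'orientation.R'
    'rve.R'
    'fe.R'
    'io.R'
    'study.R'
    'synthetic.R'
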