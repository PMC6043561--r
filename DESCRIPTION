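Package: sencluster
Title: Senescence-Nucleated 3D Tumor-Cell Clustering: Cellular Potts
    Simulation and Cell-Track Motility Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A 3D cellular Potts model in which a senescent "fried-egg"
    cell - a bulged core surrounded by a thin multi-domain body -
    secretes a diffusing chemoattractant and gathers newly divided
    tumor cells into a 3D cluster on top of its core. The lattice
    evolves by Metropolis copy kinetics under a Hamiltonian with
    volume/surface elasticity, differential type-pair interface
    energies, a chemotactic move bias coupled to a reaction-diffusion
    field, and mitotic cell-rounding adhesion schedules that relax
    exponentially after each division. The package also implements the
    accompanying cell-track statistics (ensemble mean-squared
    displacement and its anomalous exponent, two-tiered exponential
    directional persistence, radial velocity, cluster metrics) and
    synthetic-trajectory generators (two-population persistent random
    walks, exact fractional Brownian motion) so every analysis stage is
    testable without experimental imaging data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
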