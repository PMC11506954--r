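Package: perfuscaff
Title: Perfusion Flow, Wall Shear Stress and Oxygen Transport in
    Spheroid-Seeded Macroporous Hydrogel Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and image-analysis toolkit for perfused macroporous
    hydrogel scaffolds seeded with MSC/HUVEC co-culture spheroids. Generates
    synthetic voxel geometries statistically matched to OCT-derived scaffold
    reconstructions (porosity, pore size, spheroid seeding density), solves
    steady perfusion flow with a two-relaxation-time D3Q19 lattice Boltzmann
    method, evaluates wall shear stress from the non-equilibrium stress
    tensor with locally detected wall normals, solves steady
    convection-diffusion-reaction oxygen transport (D3Q7 TRT) with
    Michaelis-Menten consumption in spheroids, quantifies pore and spheroid
    morphometry (Gaussian filter, threshold, despeckle, watershed, labeling),
    and analyses 3-D cell-type point patterns with Ripley's K function
    against a Poisson reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
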