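Package: frapkd
Title: Single Intercellular-Space FRAP Analysis, Binding-Affinity Estimation
    and Morphogen-Gradient Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the mobility of secreted proteins in the
    intercellular space of embryonic tissue from fluorescence recovery after
    photobleaching (FRAP) in a single linear intercellular gap. Implements
    the closed-form one-dimensional free-diffusion recovery model and the
    two-exponential (diffusion-driven plus adsorption-driven) recovery model,
    a brute-force reaction-diffusion simulator used as ground truth,
    effective-diffusion-coefficient extraction via the two-thirds recovery
    time, equilibrium binding solvers (1:1 Langmuir isotherms, competitive
    three-species equilibria, dissociation constants from FRAP amplitude
    ratios), a receptor-competition model of a sigmoid ligand signalling
    gradient reshaped by a diffusible inhibitor, image-stack helpers (drift
    registration, trace extraction, intensity calibration, graft diffusion
    paths), and seeded synthetic-data generators for end-to-end testing.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
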