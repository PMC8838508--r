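Package: protdyn
Title: Protein Trajectory Dynamics and Infrared Spectra from Dipole
    Autocorrelation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of labelled
    proteins: least-squares (Kabsch) superposition, RMSD and RMSF
    profiles, dynamical cross-correlation maps (DCCM) and their
    differences with threshold-based feature extraction, a simplified
    harmonic force field for a linear triatomic azide vibrational probe
    (energies, analytic gradients, normal modes), and infrared spectra
    from the Fourier transform of dipole-moment autocorrelation
    functions with Blackman windowing and a harmonic quantum correction
    factor. Includes seeded synthetic-trajectory generators (correlated
    Gaussian ensembles, rigid-body motion, Langevin dynamics of the
    triatomic label) so every stage is testable without running
    molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
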