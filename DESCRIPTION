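Package: sptdyn
Title: Single-Particle Tracking Analysis of Membrane Receptor Diffusion,
    Trapping and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing single-particle tracking data from two-color
    TIRF microscopy of membrane proteins. Computes time-averaged mean square
    displacement (TAMSD) curves, fits the anomalous diffusion model
    MSD(t) = 4*D*t^alpha + 4*sigma_l^2 and classifies trajectories into
    immobile, sub-diffusive, normal and super-diffusive motion classes;
    segments trajectories into free and transiently confined (trapped) phases
    using a pairwise-distance recurrence matrix with a Monte Carlo Brownian
    false-positive filter; quantifies colocalization with image-level Manders
    coefficients, homogeneous-distribution controls and a chance-corrected
    single-molecule colocalization index against binary structure masks;
    detects transient two-channel colocalization events and classifies them by
    the diffusivity state of both partners; and generates synthetic two-color
    single-molecule data (Brownian, fractional Brownian, directed, immobile,
    two-state trapping and interacting-pair motion; fiber masks; rendered
    image sequences) with exported ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tiff,
    yaml,
    jsonlite,
    withr,
    EBImage,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
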