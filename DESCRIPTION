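Package: flagellaRD
Title: Reaction-Diffusion Modelling of the Eukaryotic Flagellar Beat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the sliding-controlled reaction-diffusion model of the
    eukaryotic flagellar beat, in which tug-of-war dynein kinetics with
    load-dependent detachment are coupled along an elastic axoneme. Provides
    closed-form linear stability theory (Hopf bifurcation of the motor
    activity), stiff method-of-lines integration of the shear-angle PDE and of
    the isolated shearable element, the no-feedback diffusion limit with its
    series solution, spectral decomposition of beating kymographs into
    fundamental Fourier modes, wavenumber and centerline reconstruction, and a
    grid-search fit of the three motor parameters against experimental-style
    tangent-angle or curvature kymographs. A seeded synthetic-data generator
    emulates the two experimental recording dialects so the full pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
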