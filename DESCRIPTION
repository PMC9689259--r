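Package: tissopt
Title: Tissue Optical Properties from Diffuse Measurements, Fluence-Rate
    Modelling, and Spectral Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates optical absorption and reduced scattering
    coefficients of turbid slabs (biological tissue) from integrating-sphere
    diffuse reflectance and total transmittance via the Kubelka-Munk two-flux
    model, in two equation dialects with exact closed-form inversion.
    Simulates steady-state surface fluence-rate distributions by solving the
    diffusion (Helmholtz) equation with linear finite elements on a graded
    triangular disk mesh with an internal-reflectance (Robin) boundary
    condition, verified against the infinite-medium Green's function and by
    the method of manufactured solutions.  Validates emission-spectra
    matrices with single-response partial least squares regression (SIMPLS).
    Ships seeded phantom generators and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
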