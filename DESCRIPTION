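Package: ferroheat
Title: Linear-Response Magnetic Loss and SAR Modelling for Polydisperse Magnetic Fluids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes magnetic losses of polydisperse superparamagnetic fluids
    in alternating and rotating magnetic fields using linear response (Debye)
    theory: Neel, Brownian and effective relaxation times, field-amplitude
    chord susceptibilities from the Langevin function, complex magnetization
    phasors, time-averaged volumetric heating power and the specific
    absorption rate (SAR), summed over log-normal particle size groups.
    Includes temperature-dependent carrier viscosity and density models,
    the calorimetric initial-slope SAR estimator used to validate the model,
    and deterministic synthetic-data generators for TEM-like size samples and
    noisy heating curves with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    jsonlite
Config/testthat/edition: 3
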