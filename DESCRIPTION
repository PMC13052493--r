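Package: fdnirs
Title: Frequency-Domain Near-Infrared Spectroscopy of Layered Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for frequency-domain near-infrared spectroscopy (FD-NIRS)
    of skeletal muscle and other layered tissues. Provides a photon-diffusion
    forward model for homogeneous and N-layer media (complex reflectance,
    AC amplitude and phase), single-distance and self-calibrating dual-slope
    probe reductions, partial generalized pathlengths and layer sensitivities,
    a two-wavelength hemoglobin inversion, estimators of blood flow (venous
    occlusion) and oxygen consumption (arterial occlusion), and a synthetic
    generator of occlusion-protocol channel time series with instrument gains
    and noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
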