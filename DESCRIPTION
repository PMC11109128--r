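Package: optorgn
Title: Broadband Optogenetic Excitation of Retinal Ganglion Neurons
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic light-to-spike simulation of channelrhodopsin-
    expressing retinal ganglion neurons. Builds parametric narrowband (LED)
    and broadband (sunlight, halogen lamp, RGB, flat white) source spectra,
    converts them to action-spectrum-weighted effective photon flux, drives
    a four-state opsin photocycle model for eleven published opsin variants,
    couples the resulting photocurrent to a Fohlmeister-Miller-type
    conductance-based retinal ganglion neuron model, and exposes the standard
    analysis protocols: voltage-clamp photocurrent metrics, EPD50, irradiance
    and pulse-width thresholds, wavelength tuning, spike latency, pulse-train
    fidelity, and high-frequency one-spike-per-pulse limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
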