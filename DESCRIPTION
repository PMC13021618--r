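Package: vibrofeed
Title: Vibration-Based Quantification and Predictive Control of Fish
    Feeding Intensity
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies the feeding intensity of farmed fish from triaxial
    water-surface vibration displacement and closes the loop on feed delivery.
    Provides amplitude-gated preprocessing and 5-second windowed summation of
    triaxial displacement series, a seeded synthetic trial generator calibrated
    to published size, density, feed-rate and pellet-size response curves,
    parametric characterization of those responses, natively implemented
    LSTM, GRU and Transformer sequence forecasters of near-future feeding
    intensity, and a predictive stop-feeding controller evaluated by residual
    feed rate against a satiation tank surrogate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
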