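Package: compscan
Title: Composite Photon Beam Profiles from Ion Chamber Arrays via Couch-Shift Interleaving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for acquiring high spatial-resolution photon beam profiles
    from a coarse ion-chamber detector array by interleaving measurements taken
    at multiple sub-pitch couch positions. Provides an analytic beam/array
    simulator (error-function penumbrae, scatter tails, horns, wedged
    gradients), the coordinate bookkeeping that maps shifted array readings
    into the radiation-isocenter frame, composite-profile reconstruction and
    renormalization, a 1D gamma-index engine with global and local
    normalization, detector-size matching by rectangular-kernel convolution,
    and repeatability/couch-shift quality-assurance statistics, together with
    a columnar text format and an end-to-end virtual scan pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
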