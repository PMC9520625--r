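Package: sonocrack
Title: Slight-Crack Seed Detection from Air-Coupled Ultrasound by Mode
    Decomposition and Color-Encoded Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive detection of slight testa cracks in cottonseed from
    air-coupled ultrasonic A-scans. A waveform is decomposed into band-limited
    intrinsic mode functions by variational mode decomposition (ADMM spectral
    updates), the mode count is selected by minimum mean sample entropy, the
    stacked mode matrix is encoded as a color-cycled polyline image over a shared
    background canvas, and a lightweight MobileViT-style vision transformer
    classifies the encoded images. Includes a seeded synthetic tone-burst echo
    generator with class-dependent carrier frequency, damping and intensity
    shifts, so the full pipeline can be exercised and validated without access
    to proprietary instrument recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
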