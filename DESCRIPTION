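Package: twinkledop
Title: Doppler Twinkling-Artifact Imaging for HIFU Thermal Lesion Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Monitors high-intensity focused ultrasound (HIFU) thermal lesions
    from sequences of beamformed radio-frequency (RF) ultrasound frames via the
    color-Doppler twinkling artifact. Extracts per-pixel slow-time signals,
    estimates Doppler frequency shifts by sliding-window spectral analysis with
    amplitude gating and consecutive-window phase differencing, renders Doppler
    frequency images, and segments and measures lesion depth and width with
    summary statistics against reference dimensions. Includes a seeded
    point-scatterer phantom generator emulating a HIFU exposure acquisition so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
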