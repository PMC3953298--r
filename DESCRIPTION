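Package: gnrhpulse
Title: Pulsatile GnRH Signalling to ERK and ERK-Driven Transcription
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic model of pulsatile gonadotropin-releasing hormone (GnRH)
    signalling through its G-protein-coupled receptor to the ERK MAP kinase
    cascade and an ERK-dependent transcriptional output. Implements a
    ten-species ordinary differential equation model with distributive dual
    (de)phosphorylation of ERK, nucleocytoplasmic ERK shuttling and negative
    feedback; square-wave pulse protocols with washout and MEK-inhibitor
    interventions; integrated-response (area-under-curve) analyses of pulse
    frequency, width and amplitude; a genetic-algorithm parameter-fitting
    routine; and a synthetic-data generator emulating live-cell ERK2-GFP
    nuclear:cytoplasmic imaging and dose-response readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
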