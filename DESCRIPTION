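Package: thermoresp
Title: Respiration Analysis from Nasal Air Temperature Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct breathing patterns of head-fixed primates
    from nasal air temperature recorded with a fast thermosensor, and to
    validate the reconstruction against a chest-band channel. Includes
    respiratory cycle extraction with sub-sample peak timing, inter-peak
    interval (IPI) and inspiration/expiration ratio estimation,
    thermosensor-versus-chest-band delay characterization, lick-artifact
    assessment via event-triggered averaging, stimulus-block contrasts of
    breathing frequency, and a ground-truthed synthetic session generator
    that emulates the recording physics (first-order sensor lag, probe
    position attenuation, weight-dependent transport delay) and the
    behavioral session protocol.
License: MIT
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
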