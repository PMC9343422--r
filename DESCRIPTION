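Package: swaysync
Title: Head-Trunk Segmentation Analysis from Multi-Sensor Postural Sway Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-point accelerometer recordings of quiet
    standing. Computes pairwise acceleration correlation and a signed
    Hilbert-phase synchronization index between body-mounted sensors, aggregates
    them across trials and subjects, bands them into similarity categories, and
    identifies coherent sensor clusters and link sites along the head-trunk
    axis. Includes a synthetic multi-segment sway simulator with known ground
    truth, orientation correction and zero-phase low-pass filtering of raw
    recordings, and a two-way repeated-measures ANOVA with Bonferroni-corrected
    post hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
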