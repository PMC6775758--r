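Package: homecage
Title: Simulation and Analysis of Automated Home-Cage Auditory Go/No-Go Training
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale model of continuous auditory operant conditioning in
    the rodent home cage. Provides a discrete-event task engine implementing
    the trial contingencies of tone detection and go/no-go frequency
    discrimination (intertrial intervals, lick-refrain periods, reward and
    timeout rules), a generative virtual-mouse model of a cage's merged lick
    stream (circadian gating, spout-contact episodes, tone-evoked responses,
    ultradian engagement oscillations), an analysis suite for timestamped lick
    and stimulus event logs (response rates, engagement, latency histograms,
    area under the latency histogram, d-prime, circadian and periodicity
    analyses, Kolmogorov-Smirnov comparisons), and an inverse-filter speaker
    whitening calibration. Event logs use plain CSV tables with a JSON
    metadata sidecar, so recorded lickometer data can be analysed with the
    same functions as simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
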