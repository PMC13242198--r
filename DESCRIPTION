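Package: posnertacs
Title: Simulation and Offline Analysis of Pre/Post tACS Posner Cueing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a sham-controlled pre/post
    transcranial alternating current stimulation (tACS) experiment built
    around a Posner visuo-spatial cueing task with concurrent EEG. Includes
    a synthetic-data generator (stratified task schedules, reaction-time
    tables, blinding surveys, and multichannel EEG epochs with scale-free
    background, band-limited alpha/gamma oscillations and N1/P3 templates),
    reaction-time cleaning and summaries, ERP component quantification
    (mean amplitude and fractional-area latency) with time-resolved paired
    tests, DPSS multitaper band power of cue-target-interval segments,
    detrended fluctuation analysis of long-range temporal correlations,
    mixed repeated-measures ANOVA with partial eta squared, cluster-based
    sensor-space permutation inference on electrode graphs, a
    continuity-corrected McNemar blinding check, a noncentral-t design
    sensitivity solver, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
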