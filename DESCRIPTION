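Package: mobsense
Title: Behavioral Feature Extraction from Smartphone and Wearable Sensor Streams
Version: 0.1.0
Authors@R: person("mobsense", "developers", role = c("aut", "cre"), email = "dev@mobsense.invalid")
Description: An end-to-end pipeline for digital phenotyping studies: ingests
    raw smartphone (AWARE-style), Fitbit, and Empatica sensor streams from
    delimited text files, localizes timestamps across multiple time zones with
    full daylight-saving support, segments time flexibly (frequency, periodic,
    and event-anchored windows), extracts a 407-feature behavioral catalog
    (calls, screen, battery, light, mobility, heart rate, steps, sleep,
    electrodermal activity, and more), quantifies per-segment data yield,
    renders five quality-control plots, and orchestrates everything through an
    incremental per-(participant, sensor) DAG. A seeded synthetic-study
    generator makes the whole pipeline testable without any real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lubridate,
    yaml,
    digest,
    stats,
    utils,
    graphics,
    parallel
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
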