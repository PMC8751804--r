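Package: h2sindex
Title: Exposure Index for Direct-Reading Hydrogen Sulphide Sensor Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Converts timestamped gas-concentration logs from direct-reading
    hydrogen sulphide (H2S) sensors into a single dimensionless exposure
    index per work shift. Shifts are segmented into exposure tasks by a
    3-minute centred moving average, distinct peaks within each task are
    detected by a two-criterion rule (strict local maximum that exceeds a
    1-minute centred moving average by a configurable ratio) and classified
    into four concentration intervals, exposed durations are accumulated in
    two intervals, and a weighted sum combines peak counts, durations and
    the shift maximum into one hazard number alongside the 8-hour
    time-weighted average. Includes CSV reading and validation for
    regular-interval logger exports, a seeded synthetic shift generator
    with an independent brute-force oracle for end-to-end testing, JSON/CSV
    reporting, and a command-line interface for single-shift, batch and
    simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
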