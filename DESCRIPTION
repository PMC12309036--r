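Package: dispersews
Title: Dispersal Detection from GPS Telemetry via Early Warning Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects dispersal events of GPS-collared animals from the net
    squared displacement (NSD) of their tracks. A rolling-window composite of
    the standardized moving standard deviation and lag-1 autocorrelation of
    the displacement series flags early warning signals of a regime shift in
    both the forward and time-reversed direction; flagged individuals are then
    evaluated with a mechanistic range-shift analysis (two-cluster fit with a
    transition window, circular use-area quantiles, and an F-test for a range
    shift). Includes an Ornstein-Uhlenbeck track simulator for stationary
    home-range residency with an optional directed relocation phase, so the
    whole pipeline can be exercised and calibrated on synthetic cohorts with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
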