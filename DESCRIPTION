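Package: sodphrv
Title: Second-Order Difference Plot Features and Ensemble 1-NN Classification of RR-Interval Series
Version: 0.1.0
Authors@R:
    person("HRV", "Tools", email = "hrv.tools@example.org", role = c("aut", "cre"))
Description: Time-domain heart-rate-variability analysis built on the second-order
    difference plot (SODP) of RR-interval series. Computes the central tendency
    measure CTM(r), the mean in-disc distance D(r), the four per-quadrant component
    measures CCTM_k(r) and SDRR; selects discriminating radii by a pooled two-sample
    t-test over a radius grid; and classifies subjects as normal or congestive heart
    failure with a leave-one-subject-out 1-nearest-neighbour ensemble (Euclidean or
    Mahalanobis distance) that votes over window realizations and over all non-empty
    feature subsets. Includes RR file reading with trend and ectopic-beat removal, a
    two-cohort synthetic RR generator so the whole pipeline is testable without
    external data, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
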