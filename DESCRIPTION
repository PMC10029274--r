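Package: darshape
Title: Geometric Categorization of Animal Diel Activity Routines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for categorizing the geometry of animal diel activity
    routines (DARs) from high-frequency relocation data. Extracts one
    trajectory per diel cycle from raw telemetry fixes (accuracy and speed
    filtering, diel segmentation, night-quality rules, flight/stop
    segmentation, endpoint averaging, subsampling), computes four scalar
    whole-path metrics (net displacement, maximum displacement, maximum
    diameter, maximum width), clusters DARs by Ward linkage with a
    within-sum-of-squares slope heuristic for choosing the number of
    clusters, derives principal-component extent/openness/elongation
    factors, and compares DAR-type distributions across demographic and
    spatial groups, including a mixed-effects model of DAR size. A
    synthetic trajectory generator emulating seven DAR archetypes supports
    testing of every pipeline stage without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
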