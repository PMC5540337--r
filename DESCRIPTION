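Package: netentry
Title: Mosquito Entry Risk Assessment for Damaged Bed Nets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative assessment of Anopheles gambiae entry risk through
    holes in insecticide-treated bed nets. Computes hole geometry metrics
    (perimeter, area, average passable width) for rectangles, circles,
    ellipses, isosceles triangles and irregular polygon outlines; converts
    them through an appearance-encounter-passage model into hourly entry
    rates per hole, per functional area and per net under a
    one-mosquito-constantly-present convention; solves for equivalent-risk
    hole diameters across net zones; refits the passage model from
    encounter/passage count data; and computes the WHOPES proportionate
    hole index (pHI) as a comparison baseline. Includes a hole-inventory
    file format (JSON/CSV), packaged damage scenarios, synthetic inventory
    and polygon generators, a stochastic entry simulator for validating the
    deterministic rates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
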