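Package: dasycrop
Title: Dasymetric Disaggregation of Administrative Crop Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disaggregates administrative-unit crop statistics (production in
    tonnes, harvested area in hectares) onto a ~1 km population grid.
    Mixed-year census values are standardised to national reference-year
    totals, converted to per-capita rates over the rural population (urban
    pixels above a density threshold are masked), allocated linearly to
    pixels, and clipped by per-pixel capacity caps with iterative
    redistribution of the excess ("water-filling"). Missing unit records are
    imputed from adjacent units or user-declared unit groups, and nodata
    holes inside declared bounding boxes are filled at a constant per-capita
    rate. A seeded synthetic-landscape generator provides population
    surfaces, admin hierarchies and census tables with known per-pixel
    ground truth, so the whole pipeline is testable without proprietary
    population or census data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
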