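Package: iceways
Title: Lake-Ice Phenology and Fine-Scale Ungulate Movement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools linking freshwater-ice phenology to the fine-scale movements
    of migratory ungulates. Computes an ice/water index from 8-day classified
    ice rasters, dates lake breakup and freeze-up from its x-intercepts, and
    fits linear trends; segments GPS trajectories near large water bodies into
    ice crossings, water crossings and detours after stopover removal; fits
    step-selection functions (conditional logistic regression on observed
    steps matched to random control steps) with AICc model comparison and
    rank-based k-fold validation; and projects the consequences of shifted
    ice phenology by flagging crossings that become impossible and replacing
    them with shortest land detours. Includes a synthetic-data module that
    generates landscapes, seasonal ice-raster series and behaviour-driven
    trajectories with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
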