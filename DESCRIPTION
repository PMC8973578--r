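Package: traplife
Title: Simulation and Analysis of Trap-Array Yeast Replicative-Aging Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for single-cell replicative-aging studies of budding yeast
    in microfluidic trap arrays. Provides a ground-truthed synthetic generator
    of trap-array time-lapse experiments (array occupancy with self-filling,
    per-cell budding and daughter-dissection timelines, frame-sampled object
    observations), a sequential two-digit event coder that converts per-frame
    bud observations into digital matrices of budding events, and the cohort
    statistics used in such studies: replicative lifespan (RLS), budding time
    intervals (BTI), viability curves, capture-time-binned RLS with linear
    regression, birth- and death-aligned BTI profiles, and BTI kymographs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
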