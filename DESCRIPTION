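Package: irgdose
Title: Intervention Dose Estimation for Health Promotion Programmes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how much of a health promotion programme was
    actually implemented, guarding against the "type III error" of judging a
    programme ineffective when it was never delivered as planned. The package
    models intervention-related groups (IRGs: one setting x intervention cell,
    active or control), plans indicator report sheets, runs an expert-panel
    consensus scoring protocol (threshold-triggered debate, second-round
    scoring, fictitious-IRG calibration of between-group effects), computes
    programme-driven and non-programme-driven intervention doses with the
    weighted delivery/participation formula, and analyses dose variability,
    active-versus-control contrasts and between-strategy interactions with
    cluster-level permutation tests. A synthetic expert-panel generator makes
    every stage testable without study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
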