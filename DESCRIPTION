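Package: interRest
Title: Intermittent Resting-State Functional Connectivity from Blocked Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives resting-state functional connectivity from the rest
    periods interleaved in a blocked-design task fMRI ("intermittent resting
    state") and validates it against continuous resting-state fMRI at three
    levels: network topography (group spatial ICA with template matching),
    within-network connectivity (Fisher-z ROI-to-ROI matrices compared by
    Spearman similarity with permutation and exact Mantel tests), and
    second-level seed-based group comparisons with permutation cluster-extent
    inference. Includes a synthetic BOLD generator with planted network
    structure, canonical-HRF task activation and structured noise, so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tools,
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
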