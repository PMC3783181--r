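Package: transens
Title: Translational Speed Profiles and Sensitivity to Fluctuating tRNA
    Availability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-codon translation rates from condition-specific
    tRNA isoacceptor availabilities (concentrations and charged fractions)
    using a tRNA-adaptation-index model under Crick wobble rules, converts
    coding sequences into raw and sliding-window-smoothed translational
    speed profiles, derives genome-wide profile features against an
    average-speed threshold (average time, slowest point, drop count,
    maximal drop length), and quantifies per-gene sensitivity of profiles
    to shifts between conditions as a length-normalised L1 distance.
    Includes deterministic synthetic generators for tRNA pools,
    growth-rate-like and starvation-like perturbations, and biased coding
    sequence sets, so the whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
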