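Package: polarcensus
Title: Dual-Platform Abundance Estimation for Onshore Polar Bears
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates polar bear abundance on ice-free Arctic islands from
    two independent platforms and compares the results. A satellite census
    treats two analysts' reviews of the same high-resolution image as a
    two-occasion closed-population mark-recapture experiment (full-likelihood
    M_t model with observer-specific detection, lognormal f0 confidence
    intervals); a helicopter line-transect survey is analysed with
    conventional and covariate distance sampling (half-normal, hazard-rate and
    uniform-plus-cosine detection functions, AICc model averaging with
    unconditional variance, and a Huggins double-observer check of perfect
    detection on the line). A seeded synthetic scene generator (island,
    bears, persistent and ephemeral confusers, transects, image pairs)
    makes the full pipeline testable without proprietary imagery, and a
    simple change-detection stage extracts bright spots present on a target
    date but absent on a reference date.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
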