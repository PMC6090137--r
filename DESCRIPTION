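Package: fbinet
Title: Nutrient-Dependent Fungal-Bacterial Interaction Networks from Co-Culture Bioassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed, weighted, bipartite fungal-bacterial interaction
    networks from colony-area measurements of plate co-culture bioassays.
    Co-culture growth is compared to monoculture controls with Welch's t-test
    per organism, partner, medium and day; day-wise significance patterns are
    graded on a signed -6..+6 strength scale; per-medium directed networks are
    assembled and summarised by connectivity, a sign-flip permutation test for
    dominance of inductions versus repressions, and Quadratic Assignment
    Procedure (QAP) permutation tests for cross-media network correlation.
    Includes a synthetic colony-growth generator with plantable induction and
    repression effects for power and calibration studies, and an
    identity-threshold rule for taxonomic rank assignment from sequence
    similarity hits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
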