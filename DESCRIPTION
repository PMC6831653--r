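Package: archipel
Title: Multi-Taxon Marine Island Biogeography from Presence/Absence Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative island biogeography from species-by-region
    presence/absence checklists: checklist validation and depth/status
    filtering, pairwise beta-diversity dissimilarities (Jaccard, Sorensen,
    Simpson, Ochiai), agglomerative clustering under four linkage schemes with
    cophenetic-correlation model selection, bootstrap node support for
    dendrograms, optimal cluster number by silhouette widths and the Mantel
    statistic, endemism and shared-endemics summaries, the molluscan
    Provincial Index Taxa / Provincial Combined Index ranking, and a synthetic
    checklist generator with planted biogeographic structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
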