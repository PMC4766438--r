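Package: odorfuse
Title: Fusing Heterogeneous Odorant-Response Datasets into Consensus Response Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining partially overlapping receptor-odorant
    response datasets, recorded in different laboratories with different
    techniques and measurement units, into a single consensus response
    matrix. Datasets are rescaled to the unit interval and merged pairwise
    by fitting monotonic functions (five families and their inverses),
    projecting shared and unique odorants onto the best-fitting curve, and
    optimizing the merge order by mean orthogonal distance. Includes
    tuning-breadth statistics (lifetime kurtosis, lifetime sparseness,
    population kurtosis), profile-matching utilities (receptor mapping,
    sensillum identification, private-odorant search), a calcium-imaging
    response-extraction pipeline (delta F/F, exponential bleach correction,
    windowed response quantification, reference-odorant drift correction),
    and seeded generators of synthetic multi-study data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
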