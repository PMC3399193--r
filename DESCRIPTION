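Package: nichecast
Title: Climate-Driven Species Range Projection with Dispersal Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting species geographic ranges under climate
    change with presence-background species distribution models. Derives six
    bioclimatic covariates from monthly temperature and precipitation grids,
    fits L1-regularised maximum-entropy models to presence-only records,
    projects fitted models onto ensembles of future climate realisations from
    multiple circulation models with realization-weighted averaging, converts
    potential to realized distributions via biogeographic subregion clipping,
    applies full, rate-limited and no-dispersal scenarios through decade-wise
    buffer masks, and summarises range change, patch structure and stacked
    species richness. Includes a synthetic-data generator (virtual landscapes,
    climate trends, virtual species with known niches, biased presence-only
    sampling) so the whole pipeline can be exercised and validated against
    known truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
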