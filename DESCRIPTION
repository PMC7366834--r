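Package: shadegrass
Title: Light Filtering and Biotic Interactions in Mapped Understory
    Grass Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mapped, twice-censused plant community
    experiments along a light gradient. Implements the change in pairwise
    Bray-Curtis dissimilarity (delta-B) with one- and two-sample t tests
    and a regression on illumination difference to detect environmental
    (light) filtering, and a kernel pair-correlation-function estimator
    with Ripley's isotropic edge correction on rectangular windows whose
    between-census change (delta-pcf) with replicate confidence bands
    classifies biotic interactions as competition or facilitation by
    spatial scale. Includes a fully seeded synthetic-experiment generator
    (shared seed bank, treatment-dependent light filtering, distance-
    dependent crowding mortality) emulating a blocked shading experiment,
    plus an end-to-end pipeline producing tidy result tables.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
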