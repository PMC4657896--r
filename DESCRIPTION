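Package: colimitr
Title: Mechanistic Model of Virus-Nutrient Co-Limitation of Microbial Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-form and Monte-Carlo tools for the individual-lineage growth
    rate of a nonmotile microbe that takes up a single limiting nutrient through
    surface receptors which double as viral entry sites. Viral invasion is
    modelled as a Brownian first-passage-time process (a two-term Levy mixture
    between an absorbing host surface and a reflecting "dining sphere"), nutrient
    uptake as diffusion-limited transport, and the two are combined into a
    growth rate that can be optimized with respect to receptor efficiency.
    Includes a seeded random-walk first-passage simulator and a branching
    lineage simulator that serve as numerical oracles for every closed form,
    regime classification (virus-negligible through virus-grazed), parameter
    sampling over observed marine ranges, sensitivity reports, and figure-style
    outputs.
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
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
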