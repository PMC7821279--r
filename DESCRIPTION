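Package: edplot
Title: Effect Direction Plots for Synthesis Without Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for vote counting by effect direction in systematic reviews
    where meta-analysis is not possible. Collapses multiple related outcomes
    within each study into a single domain-level effect direction using a
    70 percent majority rule, tallies directions across studies and applies an
    exact two-tailed binomial sign test with interpretation caveats, estimates
    the power of that test by Monte Carlo simulation, and renders the effect
    direction plot (one row per study, shaded by quality; one column per
    outcome domain, with arrows sized by intervention-group sample size) as a
    deterministic SVG document or a ggplot2 graphic.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
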