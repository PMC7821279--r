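# edplot

Vote counting by effect direction for systematic reviews that cannot be
meta-analysed, with exact sign tests, power diagnostics, and the effect
direction plot.

When a review's outcomes are conceptually similar but measured on
incompatible scales, effect *direction* — improvement, deterioration, or no
change in health — can serve as the common metric. `edplot` is for
systematic reviewers (especially of public-health and complex
interventions) who need to synthesize and present such evidence
transparently:

1. **Within-study synthesis.** Related outcomes are grouped into domains;
   each study's domain gets one direction by a 70% majority rule — positive
   if `n_pos / n ≥ 7/10` (compared exactly, in integer arithmetic), negative
   symmetrically, otherwise *unclear* (no clear effect / conflicting
   findings, the sideways arrow ◂▸).
2. **Cross-study sign test.** Per domain, studies voting positive vs
   negative are counted (unclear studies are excluded); with
   `n = n_pos + n_neg` and `k = max(n_pos, n_neg)` the exact two-tailed
   p-value is `min(1, 2 · Σ_{i=k..n} C(n,i) · (1/2)^n)`. Results carry
   caveat flags (high exclusion fraction, too few eligible studies,
   publication bias unassessed) instead of a significance verdict.
3. **Power diagnostics.** `estimate_power()` simulates reviews of k studies
   to show how little power the test has once unclear studies are
   discounted; `exact_rejection_rate()` gives the enumeration answer.
4. **The plot.** One row per study, shaded by quality (green/amber/red, or a
   colourblind-safe palette with hatch patterns); one column per domain;
   arrows ▲/▼/◂▸ sized by intervention-group sample size (large > 300,
   medium 50–300, small < 50), with outcome-count subscripts. Rendered as
   byte-deterministic SVG (`render_svg()`) or a ggplot2 graphic
   (`autoplot()`).

## Worked example

The packaged example reproduces the domain-level vote counts of a ten-study
housing improvement review (the per-study outcome lists underneath are
synthetic; see the vignette):

```r
library(edplot)

ex <- housing_example()
fit <- effdir(ex$outcomes, ex$studies)
fit
#> Effect direction synthesis: 10 studies, 3 outcome domains, 65 outcomes
#>
#>   housing_condition    9 positive / 0 negative (1 unclear excluded of 10)  p = .0039
#>   general_health       5 positive / 1 negative (1 unclear excluded of 7)  p = .2188
#>   respiratory_health   5 positive / 1 negative (4 unclear excluded of 10)  p = .2188
#>
#> Note: describe patterns of effect direction without labelling them
#> statistically significant or not; sign test p-values support, not replace,
#> transparent narrative synthesis.
```

Nine of ten studies favouring improvement is unlikely under a
chance-only null (p = .0039); a 5–1 split is entirely compatible with
chance (p = .2188), and the respiratory domain additionally excludes 4 of
10 studies as conflicting — exactly the situation in which the test
under-represents the synthesis. The plot itself:

```r
syn <- synthesize_directions(ex$outcomes, ex$studies)
write_ed_svg(layout_ed_plot(ex$studies, syn), "housing.svg")
autoplot(fit)  # ggplot2 version
```

How underpowered is the test? A unanimous 5-study review can never reach
p < 0.05; six studies are the minimum:

```r
estimate_power(k_studies = c(5, 6), p_positive = 1, p_unclear = 0,
               replicates = 1000, seed = 1)[, c("k_studies", "rejection_rate")]
#> # A tibble: 2 × 2
#>   k_studies rejection_rate
#>       <dbl>          <dbl>
#> 1         5              0
#> 2         6              1
```

A command-line front end wraps the same functions
(`validate`, `synthesize`, `plot`, `power`, `fixture`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","edplot.R",package="edplot"))')" \
  synthesize --input inst/extdata/housing_example.csv --output results.json
```

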