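---
title: "Effect direction synthesis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect direction synthesis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edplot)
```

## The problem

Roughly half of public-health systematic reviews cannot pool their outcomes
into a meta-analysis: the included studies measure conceptually similar
things (cough frequency, wheeze, night cough) on incompatible scales, with
incompatible designs. Effect *direction* — did the outcome improve,
deteriorate, or not change — survives this heterogeneity and can serve as a
common metric. `edplot` implements the complete vote-counting workflow built
on that metric: within-study synthesis of related outcomes, a cross-study
exact sign test per outcome domain, power diagnostics for that test, and the
effect direction plot itself.

Throughout the package, *positive* means an improvement in health, not a
positive regression coefficient. Harmonizing polarity (a falling symptom
score is an improvement) is the data-preparer's job, before the data reach
`read_ed_data()`.

## Within-study synthesis: the 70% rule

Each study contributes a list of outcomes per domain. The domain-level
direction is:

* **positive** if at least 70% of the outcomes in the domain are positive;
* **negative** if at least 70% are negative;
* **unclear** otherwise — no clear effect / mixed effects / conflicting
  findings, drawn as the sideways arrow `r ed_glyphs()[["unclear"]]`.

Two choices here were genuinely open and are worth recording.

**Threshold inclusivity.** The rule is stated as "70% report similar
direction" qualifying and "<70%" not qualifying, which partitions exactly at
70%: we therefore implement *greater-or-equal*, and compare
`10 * n_direction >= 7 * n_total` in integer arithmetic so that 7 outcomes
of 10 passes deterministically, with no floating-point edge behaviour.

**The denominator.** Outcomes may legitimately be recorded as `no_change`.
The default (`denominator = "all"`) counts them in the denominator, so they
dilute both directions — the conservative reading of "70% of outcomes". The
alternative (`denominator = "directional"`) restricts the denominator to
positive + negative outcomes. The switch is exposed on
`synthesize_domain()`, `synthesize_directions()`, `effdir()`, and the
command line (`--denominator`); a domain of unanimous `no_change` outcomes
is *unclear* under either setting, and `n_no_change` is always reported so a
reader can tell "all stable" apart from "conflicting".

Useful invariants, all covered by tests: the synthesis is
permutation-invariant; exactly one of the three results is returned for any
non-empty input; and flipping any outcome toward positive can never demote a
positive domain result.

## Arrow size and row shading

Arrow size encodes the final intervention-group sample size (individuals):
large for n > 300, medium for 50–300 inclusive, small for n < 50. A missing
sample size renders as a medium arrow with an explicit `*` "sample size not
reported" annotation rather than dropping the study — the plot's strength is
that it represents *every* included study, so silent omission would be worse
than an honest unknown.

Quality is constrained to exactly three levels (`high`, `moderate`, `low`)
because the row shading scheme has exactly three colours; reviews using
other appraisal scales must map into these at data-preparation time.

## The cross-study sign test

For each domain we count studies with a positive versus a negative
domain-level direction. Unclear studies are excluded — they represent
neither direction. With `n = n_pos + n_neg` eligible studies and
`k = max(n_pos, n_neg)`, the two-tailed p-value is the doubled upper tail of
Binomial(n, 1/2), capped at 1:

$$p = \min\Big(1,\; 2\sum_{i=k}^{n}\binom{n}{i}(1/2)^n\Big).$$

Under this symmetric null, doubling coincides with summing both tails, and
matches standard exact-binomial calculators; the suite verifies equivalence
with `stats::binom.test()` and with brute-force two-tail summation for every
count pair with total ≤ 25. Numerically, the tail is accumulated as an exact
integer sum of binomial coefficients for n ≤ 50 (exact in double precision)
before the single division by $2^n$; beyond 50 — far larger than any
realistic review — it falls back to `pbinom()`. Display formatting is four
decimals without the leading zero (`.0039`), with the full-precision value
always retained.

`sign_test_domains()` deliberately exposes no significant-yes/no field, and
its print method carries a fixed reminder to avoid "statistically
significant" language about direction patterns. It attaches caveat flags
instead:

* `no_eligible_studies` — p undefined, every study unclear;
* `high_exclusion_fraction` — more than half the domain's studies excluded
  (think of 20 studies of which 11 conflict: the test covers 9/20 and
  arguably misrepresents the synthesis);
* `small_k` — fewer than 6 eligible studies, because 6 is the smallest count
  at which even a unanimous review reaches p < 0.05
  ($2 \cdot (1/2)^6 = 0.03125$, versus $2 \cdot (1/2)^5 = 0.0625$);
* `publication_bias_unassessed` — on unless the caller asserts otherwise;
  the sign test should not be used when publication bias is suspected.

The 1/2 and 6 cutoffs behind the first two flags are package heuristics, not
part of the synthesis algorithm; both are arguments with these defaults.

## Power diagnostics

`estimate_power()` operationalizes the test's central weakness. Studies are
modelled i.i.d.: unclear with probability `p_unclear`, otherwise positive
with probability `p_positive`. This is the minimal model that exposes the
counting problem; it deliberately ignores between-study correlation, and the
broader critique that review-level vote counts are not truly binomial is a
documented limitation, not something we model. All randomness flows from R's
default Mersenne-Twister generator seeded once per scenario
(`seed + scenario index - 1`), so every estimate is reproducible from its
parameters and seed.

The Monte-Carlo estimate is calibrated against the exact companion
`exact_rejection_rate()`, which enumerates the binomial outcome space. Two
sharp facts make good anchors: under the null with k = 10 the true rejection
rate at α = 0.05 is $2 \cdot P(\mathrm{Bin}(10, 1/2) \ge 9) = 0.0215$ — the
discrete test is conservative — and unanimous-positive reviews have power
exactly 0 at k = 5 and exactly 1 at k = 6. The test suite checks the
Monte-Carlo rate at 10,000 replicates against enumeration within three
Monte-Carlo standard errors; monotonicity in k and in distance from the null
is checked on the exact companion to keep the run fast and noise-free.

## Rendering

`layout_ed_plot()` computes the full grid — every (study, domain) pair gets
exactly one cell, with pairs lacking data drawn as explicit empty cells —
and `render_svg()` serializes it with fixed-format geometry so that the same
layout yields byte-identical SVG. Concrete choices, all configurable:
shading colours green `#2E7D32`, amber `#F9A825`, red `#C62828` at 25%
opacity behind black text (chosen for readable contrast); glyph font sizes
10/14/19 pt for small/medium/large; the sideways arrow rendered as the
two-character sequence `r ed_glyphs()[["unclear"]]` rather than a single
double-headed arrow, for fidelity to the template convention; subscript
outcome counts shown only when a cell represents more than one outcome. A
`colorblind` palette swaps in Okabe-Ito-based colours *and* per-quality
hatch patterns so rows stay distinguishable without colour. An optional
footer renders per-domain sign-test counts and p-values; it is off by
default because the canonical plot has no such row. The legend text is fixed
and versioned so plots are self-describing.

`autoplot()` provides the same grid as a ggplot2 graphic for interactive use
and PNG export via `ggsave()`; the hand-written SVG route is the one with
the byte-determinism contract.

## The worked example and the generator

`housing_example()` ships a ten-study, three-domain dataset whose
domain-level vote counts reproduce a published re-analysis of a housing
improvement review: housing condition 9 positive / 1 unclear of 10
(p = .0039), general health 5 positive / 1 negative / 1 unclear of 7
(p = .2188), respiratory health 5 positive / 1 negative / 4 unclear of 10
(p = .2188). Only those domain-level counts are faithful: the per-study
outcome lists, designs, sample sizes, and quality ratings underneath are
synthetic (the primary studies' data are not public) and were chosen to
exercise the 70% boundary (one study synthesizes from exactly 7 positive of
10 outcomes), dilution by `no_change`, all three arrow sizes including both
300/301 and 49/50 boundaries, the unknown-n annotation, all three shading
colours, and an incomplete grid. The packaged file
`inst/extdata/housing_example.csv` is this dataset in the long input format.

`generate_review()` draws fully random reviews (i.i.d. outcome directions,
configurable per-cell outcome counts, missing domains and missing sample
sizes) for property-style tests. What passing tests on these fixtures shows
is that the *mechanics* — grouping, thresholding, exclusion, counting,
rendering — are correct; synthetic reviews have no correlated outcomes, no
selective reporting, and no relation between quality and direction, so they
say nothing about how vote counting behaves on real evidence bases. That
caution is inherent to the method, not to this implementation.

## Problem sizes in the checks

The exhaustive checks run over every direction multiset of up to 8 outcomes
(all 164 of them, with permutation checks), every sign-test count pair with
total ≤ 25 (351 pairs), closed-form unanimous votes to n = 20, and 10,000
Monte-Carlo replicates for the calibration scenario — sizes chosen so the
whole suite completes in well under a minute while covering every boundary
the algorithms have.

## Known limitations

Direction-only synthesis discards magnitude, precision, and within-study
correlation by design. The sign test inherits every caveat above and should
be read as a guard against over-interpreting patterns, not as a hypothesis
test to headline. Very large reviews overflow a single panel; the renderer
does not paginate. GRADE-style certainty assessment and any form of pooled
effect estimation are out of scope.
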