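test_that("layout maps directions, subscripts, shading, and empty cells", {
  rev <- housing_example()
  syn <- synthesize_directions(rev$outcomes, rev$studies)
  spec <- layout_ed_plot(rev$studies, syn)

  expect_s3_class(spec, "ed_plot_spec")
  expect_equal(nrow(spec$cells), 10 * 3)

  glyphs <- ed_glyphs()
  cell <- function(s, d) spec$cells[spec$cells$study_id == s &
                                      spec$cells$domain_id == d, ]
  # S01 housing condition: 3 positive outcomes -> up arrow, subscript 3
  c1 <- cell("S01", "housing_condition")
  expect_equal(c1$glyph, unname(glyphs["positive"]))
  expect_equal(c1$subscript, 3L)
  # single-outcome cells carry no subscript
  expect_true(is.na(cell("S02", "housing_condition")$subscript))
  # S10 housing condition synthesized unclear -> sideways arrow
  expect_equal(cell("S10", "housing_condition")$glyph,
               unname(glyphs["unclear"]))
  # S08 has no general_health outcomes -> explicit empty cell
  c8 <- cell("S08", "general_health")
  expect_true(c8$empty)
  expect_equal(c8$glyph, "")
  # S08's sample size is unknown -> medium arrow + annotation flag
  expect_true(cell("S08", "housing_condition")$n_unknown)
  expect_equal(cell("S08", "housing_condition")$size_class, "medium")

  shade <- ed_palette("traffic")
  expect_equal(
    spec$rows$shade_hex,
    unname(shade[rev$studies$quality])
  )

  expect_error(
    layout_ed_plot(rev$studies[-1, ], syn),
    "no metadata"
  )
  expect_error(
    layout_ed_plot(rev$studies, syn, characteristic_columns = c(X = "nope")),
    "nope"
  )
})

test_that("row sorting orders by quality then study id", {
  rev <- housing_example()
  syn <- synthesize_directions(rev$outcomes, rev$studies)
  spec <- layout_ed_plot(rev$studies, syn, sort_rows = TRUE)
  qualities <- spec$rows$quality
  expect_equal(qualities, sort(factor(qualities, ed_qualities()) |>
                                 as.integer()) |>
                 (\(i) ed_qualities()[i])())
  within_high <- spec$rows$study_id[qualities == "high"]
  expect_equal(within_high, sort(within_high))
})

test_that("SVG rendering is deterministic and complete", {
  rev <- housing_example()
  syn <- synthesize_directions(rev$outcomes, rev$studies)
  spec <- layout_ed_plot(rev$studies, syn)
  svg1 <- render_svg(spec)
  svg2 <- render_svg(spec)
  expect_identical(svg1, svg2)

  n_cells <- lengths(regmatches(svg1, gregexpr('class="domain-cell"', svg1)))
  expect_equal(n_cells, 10 * 3)
  n_rows <- lengths(regmatches(svg1, gregexpr('class="study-row"', svg1)))
  expect_equal(n_rows, 10)
  expect_match(svg1, 'class="legend-line"')
  # three distinct glyph font sizes are in play
  for (size in c("10.0", "14.0", "19.0")) {
    expect_match(svg1, paste0('font-size="', size, '"'))
  }
  # only the three direction glyphs appear as arrows
  glyph_chars <- unlist(strsplit(ed_glyphs(), ""))
  pattern <- paste0("[", paste(glyph_chars, collapse = ""), "]")
  glyphs_seen <- regmatches(svg1, gregexpr(pattern, svg1))[[1]]
  expect_true(all(glyphs_seen %in% glyph_chars))
  expect_gt(length(glyphs_seen), 0)

  path <- withr::local_tempfile(fileext = ".svg")
  write_ed_svg(spec, path)
  expect_identical(readChar(path, file.size(path), useBytes = TRUE), svg1)
})

test_that("grid completeness holds on randomized fixtures", {
  for (seed in 1:4) {
    rev <- generate_review(
      n_studies = sample(3:9, 1), domains = paste0("d", 1:sample(2:4, 1)),
      p_domain_missing = 0.3, seed = seed
    )
    syn <- synthesize_directions(rev$outcomes, rev$studies)
    spec <- layout_ed_plot(rev$studies, syn)
    svg <- render_svg(spec)
    n_cells <- lengths(regmatches(svg, gregexpr('class="domain-cell"', svg)))
    expect_equal(n_cells, nrow(rev$studies) * nrow(spec$domains),
                 label = paste("seed", seed))
  }
})

test_that("the colorblind palette removes traffic hexes and adds patterns", {
  rev <- housing_example()
  syn <- synthesize_directions(rev$outcomes, rev$studies)
  svg <- render_svg(layout_ed_plot(rev$studies, syn, palette = "colorblind"))
  for (hex in ed_palette("traffic")) {
    expect_false(grepl(hex, svg, fixed = TRUE))
  }
  expect_match(svg, "<pattern id=\"hatch-high\"")
})

test_that("the sign-test footer renders counts and p-values when requested", {
  rev <- housing_example()
  fit <- effdir(rev$outcomes, rev$studies)
  spec <- layout_ed_plot(rev$studies, fit$syntheses,
                         sign_tests = fit$sign_tests)
  svg <- render_svg(spec)
  expect_match(svg, "9 positive / 0 negative \\(1 excluded\\), p = .0039")
  # off by default
  svg0 <- render_svg(layout_ed_plot(rev$studies, fit$syntheses))
  expect_false(grepl("sign-test-row", svg0))
})

test_that("autoplot returns a complete ggplot grid", {
  rev <- housing_example()
  fit <- effdir(rev$outcomes, rev$studies)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(p$data), 10 * 3)
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[1]]), 10 * 3)
})
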