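#' Row-shading palettes for study quality
#'
#' `"traffic"` is the classic scheme: green for high quality / low risk of
#' bias, amber for moderate / some concerns, red for low quality / high risk
#' of bias. `"colorblind"` swaps in an Okabe-Ito-based palette and (in the
#' SVG renderer) adds distinct hatch patterns per quality level so rows
#' remain distinguishable without colour.
#'
#' @param palette `"traffic"` or `"colorblind"`.
#' @return Named character vector of hex colours for `high`, `moderate`,
#'   `low`.
#' @examples
#' ed_palette("traffic")
#' @export
ed_palette <- function(palette = c("traffic", "colorblind")) {
  palette <- match.arg(palette)
  switch(palette,
    traffic = c(high = "#2E7D32", moderate = "#F9A825", low = "#C62828"),
    colorblind = c(high = "#0072B2", moderate = "#E69F00", low = "#CC79A7")
  )
}

#' Lay out the effect direction plot grid
#'
#' Builds the renderable description of an effect direction plot from study
#' metadata and domain syntheses: one row per study (with its quality shading
#' colour), leading characteristic columns, and one cell per (study, domain)
#' pair. Cells carry the arrow glyph for the synthesized direction, the size
#' class from the intervention-group sample size, a subscript with the
#' number of outcomes the arrow represents (shown only when more than one),
#' and an "n unknown" marker for studies without a reported sample size.
#' Study-domain pairs with no synthesized data become explicit empty cells —
#' every study stays visible in every column, which is the plot's point.
#'
#' @param studies data frame of study metadata (row order = plot row order
#'   unless `sort_rows = TRUE`, which orders by quality high-to-low then
#'   `study_id`).
#' @param syntheses tibble from [synthesize_directions()] (must include
#'   `size_class`, i.e. be built with `studies` supplied).
#' @param characteristic_columns named character vector mapping column
#'   headers to `studies` column names; default shows design and
#'   intervention-group n.
#' @param domain_labels optional named character vector mapping `domain_id`
#'   to a display label.
#' @param sort_rows reorder rows by quality then study id.
#' @param palette passed to [ed_palette()].
#' @param glyph_sizes numeric vector of three font sizes (points) for
#'   small/medium/large arrows.
#' @param sign_tests optional tibble from [sign_test_domains()]; when given,
#'   a footer block with per-domain counts and p-values is rendered (off by
#'   default because the canonical plot has no such row).
#' @return An `ed_plot_spec` object: list of tibbles `rows`,
#'   `characteristics`, `domains`, `cells`, plus `legend` text lines and
#'   rendering `options`.
#' @examples
#' ex <- housing_example()
#' syn <- synthesize_directions(ex$outcomes, ex$studies)
#' spec <- layout_ed_plot(ex$studies, syn)
#' spec$cells
#' @export
layout_ed_plot <- function(studies, syntheses,
                           characteristic_columns = c(
                             "Design" = "design",
                             "N (intervention)" = "n_intervention"
                           ),
                           domain_labels = NULL,
                           sort_rows = FALSE,
                           palette = c("traffic", "colorblind"),
                           glyph_sizes = c(small = 10, medium = 14, large = 19),
                           sign_tests = NULL) {
  palette <- match.arg(palette)
  studies <- as_tibble(studies)
  syntheses <- as_tibble(syntheses)
  if (anyDuplicated(studies$study_id)) {
    stop("duplicate study_id in studies", call. = FALSE)
  }
  missing_meta <- setdiff(syntheses$study_id, studies$study_id)
  if (length(missing_meta)) {
    stop("synthesis references study with no metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  if (!"size_class" %in% names(syntheses)) {
    syntheses <- syntheses |>
      left_join(studies |> select("study_id", "n_intervention"),
                by = "study_id") |>
      mutate(size_class = arrow_size_class(.data$n_intervention),
             n_known = !is.na(.data$n_intervention)) |>
      select(-"n_intervention")
  }

  shade <- ed_palette(palette)
  rows <- studies |>
    mutate(shade_hex = unname(shade[as.character(.data$quality)]))
  if (sort_rows) {
    rows <- rows |>
      mutate(.q = match(.data$quality, ed_qualities())) |>
      arrange(.data$.q, .data$study_id) |>
      select(-".q")
  }
  rows <- rows |> mutate(row_index = dplyr::row_number())

  domain_ids <- unique(syntheses$domain_id)
  domains <- tibble(
    domain_id = domain_ids,
    label = if (is.null(domain_labels)) {
      domain_ids
    } else {
      ifelse(domain_ids %in% names(domain_labels),
             domain_labels[domain_ids], domain_ids)
    }
  )

  glyphs <- ed_glyphs()
  cells <- tidyr::expand_grid(
    study_id = rows$study_id, domain_id = domains$domain_id
  ) |>
    left_join(
      syntheses |>
        select("study_id", "domain_id", "direction", "n_outcomes",
               "size_class", "n_known"),
      by = c("study_id", "domain_id")
    ) |>
    mutate(
      empty = is.na(.data$direction),
      glyph = ifelse(.data$empty, "", unname(glyphs[.data$direction])),
      subscript = ifelse(!.data$empty & .data$n_outcomes > 1L,
                         .data$n_outcomes, NA_integer_),
      size_class = ifelse(.data$empty, NA_character_, .data$size_class),
      n_unknown = !.data$empty & !.data$n_known
    ) |>
    select("study_id", "domain_id", "glyph", "size_class", "subscript",
           "n_unknown", "empty")

  characteristics <- tibble(
    label = names(characteristic_columns),
    column = unname(characteristic_columns)
  )
  bad_col <- setdiff(characteristics$column, names(studies))
  if (length(bad_col)) {
    stop("characteristic column(s) not in studies: ",
         paste(bad_col, collapse = ", "), call. = FALSE)
  }

  legend <- c(
    paste0(glyphs[["positive"]], " positive health impact   ",
           glyphs[["negative"]], " negative health impact   ",
           glyphs[["unclear"]], " no change / mixed effects / conflicting findings"),
    paste0("Arrow size, final sample size (individuals) in intervention group: ",
           "large > 300; medium 50-300; small < 50; * sample size not reported"),
    "Subscript: number of outcomes represented by the arrow (shown when > 1)",
    paste0("Row shading (", palette, "): high quality / low risk of bias; ",
           "moderate quality / some concerns; low quality / high risk of bias"),
    paste0("edplot legend v1; ", ed_caveat_note())
  )

  structure(
    list(
      rows = rows,
      characteristics = characteristics,
      domains = domains,
      cells = cells,
      sign_tests = sign_tests,
      legend = legend,
      options = list(palette = palette, glyph_sizes = glyph_sizes)
    ),
    class = "ed_plot_spec"
  )
}

#' @export
print.ed_plot_spec <- function(x, ...) {
  cat("Effect direction plot layout:", nrow(x$rows), "study rows x",
      nrow(x$domains), "domain columns (+", nrow(x$characteristics),
      "characteristic columns)\n")
  cat("Palette:", x$options$palette,
      if (!is.null(x$sign_tests)) "; sign-test footer enabled", "\n")
  invisible(x)
}
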