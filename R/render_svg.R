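#' Render an effect direction plot layout to SVG
#'
#' Produces an SVG 1.1 document from an [layout_ed_plot()] spec. Rendering is
#' fully deterministic: the same spec yields byte-identical output, because
#' all geometry is computed with fixed-format printing and no device, font
#' metric, or locale state is consulted. Each study row gets a background
#' rectangle in its quality shading colour (25% opacity behind black text);
#' each (study, domain) pair gets exactly one cell group — empty cells are
#' rendered as explicit empty groups, never skipped — and arrow glyphs use
#' three distinct font sizes for the small/medium/large classes. With the
#' colourblind palette, rows additionally receive per-quality hatch
#' patterns. The legend block is always present.
#'
#' @param spec an `ed_plot_spec`.
#' @return Length-1 character vector: the SVG document text.
#' @examples
#' ex <- housing_example()
#' syn <- synthesize_directions(ex$outcomes, ex$studies)
#' svg <- render_svg(layout_ed_plot(ex$studies, syn))
#' substr(svg, 1, 60)
#' @export
render_svg <- function(spec) {
  stopifnot(inherits(spec, "ed_plot_spec"))
  num <- function(x) sprintf("%.1f", x)

  # fixed geometry (px)
  row_h <- 28
  header_h <- 34
  id_w <- 90
  char_w <- 110
  dom_w <- 96
  margin <- 12
  legend_line_h <- 15

  n_rows <- nrow(spec$rows)
  n_char <- nrow(spec$characteristics)
  n_dom <- nrow(spec$domains)
  footer <- spec$sign_tests
  n_footer <- if (is.null(footer)) 0L else nrow(footer)

  grid_w <- id_w + n_char * char_w + n_dom * dom_w
  grid_x0 <- margin
  grid_y0 <- margin + header_h
  grid_h <- n_rows * row_h
  footer_h <- if (n_footer) (n_footer + 1L) * legend_line_h + 8 else 0
  legend_y0 <- grid_y0 + grid_h + footer_h + 18
  total_w <- grid_w + 2 * margin
  total_h <- legend_y0 + length(spec$legend) * legend_line_h + margin

  glyph_sizes <- spec$options$glyph_sizes
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }

  out <- character()
  push <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="',
       num(total_w), '" height="', num(total_h), '" viewBox="0 0 ',
       num(total_w), " ", num(total_h), '">')
  push('<style>text{font-family:"DejaVu Sans",sans-serif;fill:#000000;}</style>')

  use_patterns <- spec$options$palette == "colorblind"
  if (use_patterns) {
    push("<defs>")
    pat <- c(high = "M0,4 L4,0", moderate = "M0,0 L4,4",
             low = "M2,0 L2,4 M0,2 L4,2")
    for (q in ed_qualities()) {
      push('<pattern id="hatch-', q,
           '" width="4" height="4" patternUnits="userSpaceOnUse">',
           '<path d="', pat[[q]],
           '" stroke="#000000" stroke-width="0.4" stroke-opacity="0.35"/>',
           "</pattern>")
    }
    push("</defs>")
  }

  # column headers
  col_x <- function(j) grid_x0 + id_w + (j - 1) * char_w       # char col j left
  dom_x <- function(j) grid_x0 + id_w + n_char * char_w + (j - 1) * dom_w
  hy <- margin + header_h - 12
  push('<text x="', num(grid_x0 + 4), '" y="', num(hy),
       '" font-size="12" font-weight="bold">Study</text>')
  for (j in seq_len(n_char)) {
    push('<text x="', num(col_x(j) + 4), '" y="', num(hy),
         '" font-size="12" font-weight="bold">',
         esc(spec$characteristics$label[j]), "</text>")
  }
  for (j in seq_len(n_dom)) {
    push('<text x="', num(dom_x(j) + dom_w / 2), '" y="', num(hy),
         '" font-size="12" font-weight="bold" text-anchor="middle">',
         esc(spec$domains$label[j]), "</text>")
  }

  # study rows
  for (i in seq_len(n_rows)) {
    row <- spec$rows[i, ]
    y0 <- grid_y0 + (i - 1) * row_h
    push('<g class="study-row" data-study="', esc(row$study_id), '">')
    push('<rect x="', num(grid_x0), '" y="', num(y0), '" width="',
         num(grid_w), '" height="', num(row_h), '" fill="', row$shade_hex,
         '" fill-opacity="0.25"/>')
    if (use_patterns) {
      push('<rect x="', num(grid_x0), '" y="', num(y0), '" width="',
           num(grid_w), '" height="', num(row_h), '" fill="url(#hatch-',
           as.character(row$quality), ')"/>')
    }
    ty <- y0 + row_h / 2 + 4
    push('<text x="', num(grid_x0 + 4), '" y="', num(ty),
         '" font-size="11">', esc(row$study_id), "</text>")
    for (j in seq_len(n_char)) {
      val <- row[[spec$characteristics$column[j]]]
      txt <- if (is.na(val)) "\u2014" else as.character(val)
      push('<text x="', num(col_x(j) + 4), '" y="', num(ty),
           '" font-size="11">', esc(txt), "</text>")
    }

    cells <- spec$cells |> filter(.data$study_id == row$study_id)
    for (j in seq_len(n_dom)) {
      cell <- cells |> filter(.data$domain_id == spec$domains$domain_id[j])
      cx <- dom_x(j) + dom_w / 2
      push('<g class="domain-cell" data-study="', esc(row$study_id),
           '" data-domain="', esc(spec$domains$domain_id[j]), '">')
      if (!cell$empty) {
        fs <- glyph_sizes[[cell$size_class]]
        label <- cell$glyph
        push('<text x="', num(cx), '" y="', num(ty),
             '" font-size="', num(fs), '" text-anchor="middle">',
             esc(label),
             if (!is.na(cell$subscript)) {
               paste0('<tspan font-size="', num(fs * 0.6),
                      '" baseline-shift="sub">', cell$subscript, "</tspan>")
             } else "",
             if (cell$n_unknown) {
               paste0('<tspan font-size="', num(fs * 0.6), '">*</tspan>')
             } else "",
             "</text>")
      }
      push("</g>")
    }
    push("</g>")
  }

  # grid lines
  for (i in 0:n_rows) {
    y <- grid_y0 + i * row_h
    push('<line x1="', num(grid_x0), '" y1="', num(y), '" x2="',
         num(grid_x0 + grid_w), '" y2="', num(y),
         '" stroke="#666666" stroke-width="0.5"/>')
  }
  xs <- c(grid_x0, grid_x0 + id_w,
          grid_x0 + id_w + seq_len(n_char) * char_w,
          grid_x0 + id_w + n_char * char_w + seq_len(n_dom) * dom_w)
  for (x in xs) {
    push('<line x1="', num(x), '" y1="', num(grid_y0), '" x2="', num(x),
         '" y2="', num(grid_y0 + grid_h),
         '" stroke="#666666" stroke-width="0.5"/>')
  }

  # optional sign-test footer
  if (n_footer) {
    fy <- grid_y0 + grid_h + legend_line_h
    push('<text x="', num(grid_x0), '" y="', num(fy),
         '" font-size="11" font-weight="bold">Sign tests (unclear studies excluded)</text>')
    for (i in seq_len(n_footer)) {
      st <- footer[i, ]
      flags <- setdiff(st$caveats[[1]], "publication_bias_unassessed")
      push('<text x="', num(grid_x0), '" y="',
           num(fy + i * legend_line_h), '" font-size="11" class="sign-test-row">',
           esc(paste0(
             st$domain_id, ": ", st$n_positive_studies, " positive / ",
             st$n_negative_studies, " negative (", st$n_excluded_unclear,
             " excluded), p = ",
             ifelse(is.na(st$p_display), "undefined", st$p_display),
             if (length(flags)) {
               paste0(" \u2020", paste(flags, collapse = " \u2020"))
             } else ""
           )), "</text>")
    }
  }

  # legend
  for (i in seq_along(spec$legend)) {
    push('<text x="', num(grid_x0), '" y="',
         num(legend_y0 + (i - 1) * legend_line_h),
         '" font-size="10" class="legend-line">', esc(spec$legend[i]),
         "</text>")
  }

  push("</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write an effect direction plot to an SVG file
#'
#' @param spec an `ed_plot_spec` from [layout_ed_plot()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ed_svg <- function(spec, path) {
  writeLines(render_svg(spec), path, sep = "", useBytes = FALSE)
  invisible(path)
}
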