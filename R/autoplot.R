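#' ggplot2 rendering of effect direction results
#'
#' `autoplot()` on an [effdir()] object (or on an `ed_plot_spec`) draws the
#' effect direction plot as a ggplot2 graphic: tiles shaded by study quality,
#' arrow glyphs sized by the three sample-size classes, and outcome-count
#' subscripts appended to the glyph where a cell represents more than one
#' outcome. The hand-written SVG route ([render_svg()]) is the canonical,
#' byte-deterministic artefact; this route is for interactive work and for
#' raster (PNG) export via [ggplot2::ggsave()].
#'
#' @param object an `effdir` or `ed_plot_spec` object.
#' @param palette passed to [ed_palette()] (for `effdir` input).
#' @param ... unused.
#' @return A ggplot object.
#' @examples
#' ex <- housing_example()
#' autoplot(effdir(ex$outcomes, ex$studies))
#' @method autoplot effdir
#' @export
autoplot.effdir <- function(object, palette = c("traffic", "colorblind"),
                            ...) {
  palette <- match.arg(palette)
  spec <- layout_ed_plot(object$studies, object$syntheses, palette = palette)
  autoplot(spec, ...)
}

#' @rdname autoplot.effdir
#' @method autoplot ed_plot_spec
#' @export
autoplot.ed_plot_spec <- function(object, ...) {
  rows <- object$rows
  cells <- object$cells |>
    left_join(rows |> select("study_id", "quality", "row_index"),
              by = "study_id") |>
    left_join(object$domains |> rename(domain_label = "label"),
              by = "domain_id") |>
    mutate(
      cell_label = ifelse(.data$empty, "",
                     paste0(.data$glyph,
                            ifelse(is.na(.data$subscript), "",
                                   as.character(.data$subscript)),
                            ifelse(.data$n_unknown, "*", ""))),
      size_pt = dplyr::coalesce(
        unname(object$options$glyph_sizes[.data$size_class]), 0
      )
    )
  shade <- ed_palette(object$options$palette)
  ggplot2::ggplot(cells, ggplot2::aes(
    x = factor(.data$domain_label, levels = object$domains$label),
    y = factor(.data$study_id, levels = rev(rows$study_id))
  )) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$quality),
                       colour = "grey40", alpha = 0.35) +
    ggplot2::geom_text(ggplot2::aes(label = .data$cell_label,
                                    size = .data$size_pt)) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_fill_manual(
      values = shade, breaks = ed_qualities(),
      name = "Quality / risk of bias"
    ) +
    ggplot2::scale_x_discrete(position = "top") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}
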