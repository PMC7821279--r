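#' Direction labels and arrow glyphs
#'
#' Raw outcomes are recorded with one of three directions: `"positive"`
#' (improvement in the health outcome), `"negative"` (deterioration), or
#' `"no_change"`. Within-study synthesis may additionally produce
#' `"unclear"`, meaning no change / mixed effects / conflicting findings;
#' `"unclear"` is never a valid raw outcome label. Positivity always refers
#' to health impact, not to the sign of the underlying estimate: outcomes
#' measured on a "lower is better" scale must be polarity-harmonized before
#' entry.
#'
#' @return `ed_directions()` returns the valid raw labels;
#'   `ed_directions(domain = TRUE)` adds `"unclear"`. `ed_glyphs()` returns a
#'   named character vector mapping domain-level directions to the plot
#'   glyphs: upward arrow (positive), downward arrow (negative), and the
#'   two-character sideways arrow (unclear).
#' @param domain if `TRUE`, include the domain-level `"unclear"` label.
#' @examples
#' ed_directions()
#' ed_glyphs()[["positive"]]
#' @export
ed_directions <- function(domain = FALSE) {
  raw <- c("positive", "negative", "no_change")
  if (domain) c(raw, "unclear") else raw
}

#' @rdname ed_directions
#' @export
ed_glyphs <- function() {
  c(positive = "\u25B2", negative = "\u25BC", unclear = "\u25C2\u25B8")
}

# three quality levels, matching the three-colour row shading
ed_qualities <- function() c("high", "moderate", "low")

ed_size_classes <- function() c("small", "medium", "large")
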