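#' Run the full effect direction synthesis pipeline
#'
#' Validates the dataset, collapses each study's outcomes to domain-level
#' directions ([synthesize_directions()]), and runs the per-domain sign tests
#' ([sign_test_domains()]). The returned object prints a compact per-domain
#' summary and supports [generics::tidy()] (per study-domain syntheses),
#' [generics::glance()] (one-row review summary), and
#' [ggplot2::autoplot()] (the effect direction plot).
#'
#' @param outcomes data frame with one row per measured outcome: `study_id`,
#'   `domain_id`, `outcome_name`, `direction`.
#' @param studies data frame with one row per study: `study_id`, `design`,
#'   `n_intervention`, `quality`.
#' @inheritParams synthesize_domain
#' @inheritParams sign_test_domains
#' @return An object of class `effdir`: a list with `outcomes`, `studies`,
#'   `syntheses`, `sign_tests`, and the `denominator` used.
#' @examples
#' ex <- housing_example()
#' fit <- effdir(ex$outcomes, ex$studies)
#' fit
#' tidy(fit)
#' glance(fit)
#' @export
effdir <- function(outcomes, studies, denominator = c("all", "directional"),
                   publication_bias_assessed = FALSE) {
  denominator <- match.arg(denominator)
  assert_valid_ed(outcomes, studies)
  syntheses <- synthesize_directions(outcomes, studies,
                                     denominator = denominator)
  sign_tests <- sign_test_domains(
    syntheses, publication_bias_assessed = publication_bias_assessed
  )
  structure(
    list(
      outcomes = as_tibble(outcomes),
      studies = as_tibble(studies),
      syntheses = syntheses,
      sign_tests = sign_tests,
      denominator = denominator
    ),
    class = "effdir"
  )
}

#' @export
print.effdir <- function(x, ...) {
  cat("Effect direction synthesis:",
      nrow(x$studies), "studies,",
      length(unique(x$syntheses$domain_id)), "outcome domains,",
      nrow(x$outcomes), "outcomes\n\n")
  st <- x$sign_tests
  for (i in seq_len(nrow(st))) {
    flags <- setdiff(st$caveats[[i]], "publication_bias_unassessed")
    cat(sprintf(
      "  %-20s %d positive / %d negative (%d unclear excluded of %d)  p = %s%s\n",
      st$domain_id[i], st$n_positive_studies[i], st$n_negative_studies[i],
      st$n_excluded_unclear[i], st$n_total_studies[i],
      ifelse(is.na(st$p_display[i]), "undefined", st$p_display[i]),
      if (length(flags)) paste0("  [", paste(flags, collapse = ", "), "]") else ""
    ))
  }
  cat("\n", ed_caveat_note(), "\n", sep = "")
  invisible(x)
}

#' Tidy an effect direction synthesis
#'
#' @param x an `effdir` object.
#' @param ... unused.
#' @return The per-(study, domain) synthesis tibble: direction, outcome
#'   counts, majority fraction, size class.
#' @method tidy effdir
#' @export
tidy.effdir <- function(x, ...) {
  x$syntheses
}

#' One-row summary of an effect direction synthesis
#'
#' @param x an `effdir` object.
#' @param ... unused.
#' @return A one-row tibble: numbers of studies, domains, outcomes, the
#'   number of domains with a defined sign test, and the smallest defined
#'   p-value.
#' @method glance effdir
#' @export
glance.effdir <- function(x, ...) {
  p <- x$sign_tests$p_two_tailed
  tibble(
    n_studies = nrow(x$studies),
    n_domains = nrow(x$sign_tests),
    n_outcomes = nrow(x$outcomes),
    n_domains_tested = sum(!is.na(p)),
    min_p = if (any(!is.na(p))) min(p, na.rm = TRUE) else NA_real_
  )
}
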