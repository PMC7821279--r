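#' Collapse one study's outcomes in a domain to a single direction
#'
#' Applies the within-study synthesis rule to a vector of raw outcome
#' directions: the domain-level direction is `"positive"` (or `"negative"`)
#' when at least 70% of the outcomes report that direction, and `"unclear"`
#' (no clear effect / conflicting findings, drawn as the sideways arrow)
#' otherwise. The comparison is exact — `10 * max_count >= 7 * n` in integer
#' arithmetic — so 7 of 10 outcomes passes deterministically, with no
#' floating-point behaviour at the boundary.
#'
#' With `denominator = "all"` (the default) the 70% share is taken over all
#' outcomes in the domain, so `"no_change"` outcomes dilute both directions;
#' with `"directional"` the share is taken over positive + negative outcomes
#' only. A domain whose outcomes are unanimously `"no_change"` is returned as
#' `"unclear"` under either setting (the sideways arrow legend covers "no
#' change" as well as "mixed"); `n_no_change` is reported so callers can
#' distinguish the two situations.
#'
#' @param directions character vector of raw directions (see
#'   [ed_directions()]); must be non-empty.
#' @param denominator `"all"` or `"directional"`: which outcomes count in the
#'   denominator of the 70% rule.
#' @return One-row tibble with `direction`, `n_outcomes`, `n_positive`,
#'   `n_negative`, `n_no_change`, and `majority_fraction`
#'   (`max(n_positive, n_negative)` over the chosen denominator; `NA` when
#'   the denominator is empty).
#' @examples
#' synthesize_domain(c("positive", "positive", "positive"))
#' synthesize_domain(rep(c("positive", "negative"), c(6, 4))) # unclear
#' @export
synthesize_domain <- function(directions, denominator = c("all", "directional")) {
  denominator <- match.arg(denominator)
  directions <- as.character(directions)
  if (length(directions) == 0L) {
    stop("cannot synthesize a domain with no outcomes", call. = FALSE)
  }
  bad <- setdiff(unique(directions), ed_directions())
  if (length(bad)) {
    stop("invalid raw direction label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_pos <- sum(directions == "positive")
  n_neg <- sum(directions == "negative")
  n_nc <- sum(directions == "no_change")
  n <- length(directions)
  denom <- if (denominator == "all") n else n_pos + n_neg
  top <- max(n_pos, n_neg)

  direction <- "unclear"
  if (denom > 0L) {
    # exact rational comparison: top/denom >= 7/10
    if (10L * n_pos >= 7L * denom) direction <- "positive"
    else if (10L * n_neg >= 7L * denom) direction <- "negative"
  }
  tibble(
    direction = direction,
    n_outcomes = n,
    n_positive = n_pos,
    n_negative = n_neg,
    n_no_change = n_nc,
    majority_fraction = if (denom > 0L) top / denom else NA_real_
  )
}

#' Arrow size class from intervention-group sample size
#'
#' Maps the final intervention-group sample size (individuals) to the three
#' arrow sizes of the effect direction plot: `"large"` for n > 300,
#' `"medium"` for 50–300 inclusive, `"small"` for n < 50. A missing sample
#' size maps to `"medium"`; callers should carry an explicit "n unknown"
#' annotation for such studies rather than dropping them (the plot's point is
#' to represent every included study).
#'
#' @param n_intervention integer vector of sample sizes; `NA` allowed.
#' @return Character vector of `"small"`, `"medium"`, `"large"`.
#' @examples
#' arrow_size_class(c(301, 300, 50, 49, NA))
#' @export
arrow_size_class <- function(n_intervention) {
  if (any(!is.na(n_intervention) & n_intervention < 0)) {
    stop("n_intervention must be non-negative", call. = FALSE)
  }
  dplyr::case_when(
    is.na(n_intervention) ~ "medium",
    n_intervention > 300 ~ "large",
    n_intervention >= 50 ~ "medium",
    TRUE ~ "small"
  )
}

#' Within-study synthesis across a whole dataset
#'
#' Groups outcome rows by `(study_id, domain_id)` and applies
#' [synthesize_domain()] to each group, then attaches the arrow size class
#' from the study's intervention-group sample size. This is step 1 of
#' producing an effect direction plot; the result feeds both
#' [sign_test_domains()] and [layout_ed_plot()].
#'
#' @param outcomes data frame of outcome rows (`study_id`, `domain_id`,
#'   `outcome_name`, `direction`).
#' @param studies optional data frame of study metadata; when supplied the
#'   dataset is validated and `size_class` / `n_known` columns are added.
#' @inheritParams synthesize_domain
#' @return A tibble with one row per (study, domain): the columns of
#'   [synthesize_domain()] plus `study_id`, `domain_id`, and — when `studies`
#'   is given — `size_class` and `n_known` (`FALSE` when the sample size is
#'   missing). Row order follows first appearance in `outcomes`, so the
#'   result is order-stable but grouping itself is order-invariant.
#' @examples
#' ex <- housing_example()
#' synthesize_directions(ex$outcomes, ex$studies)
#' @export
synthesize_directions <- function(outcomes, studies = NULL,
                                  denominator = c("all", "directional")) {
  denominator <- match.arg(denominator)
  outcomes <- as_tibble(outcomes)
  if (!is.null(studies)) assert_valid_ed(outcomes, studies)
  if (nrow(outcomes) == 0L) {
    stop("no outcomes to synthesize", call. = FALSE)
  }

  res <- outcomes |>
    mutate(.group_order = match(
      paste(.data$study_id, .data$domain_id, sep = "\r"),
      unique(paste(.data$study_id, .data$domain_id, sep = "\r"))
    )) |>
    group_by(.data$study_id, .data$domain_id, .data$.group_order) |>
    summarise(synthesize_domain(.data$direction, denominator = denominator),
              .groups = "drop") |>
    arrange(.data$.group_order) |>
    select(-".group_order")

  if (!is.null(studies)) {
    studies <- as_tibble(studies)
    res <- res |>
      left_join(studies |> select("study_id", "n_intervention"),
                by = "study_id") |>
      mutate(
        size_class = arrow_size_class(.data$n_intervention),
        n_known = !is.na(.data$n_intervention)
      ) |>
      select(-"n_intervention")
  }
  res
}
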