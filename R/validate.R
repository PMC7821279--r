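#' Validate an effect direction dataset
#'
#' Checks a long-format outcome table and its companion study table against
#' the structural rules every other function in the package assumes:
#'
#' * `outcomes` has columns `study_id`, `domain_id`, `outcome_name`,
#'   `direction`; `studies` has `study_id`, `design`, `n_intervention`,
#'   `quality`.
#' * `study_id` and `domain_id` are non-empty strings.
#' * `direction` is a raw label from [ed_directions()] — `"unclear"` is a
#'   synthesis result, never an input.
#' * `(study_id, domain_id, outcome_name)` is unique.
#' * Every outcome's `study_id` has exactly one row of study metadata.
#' * `n_intervention` is a non-negative whole number or `NA` (unknown sample
#'   size is allowed and later rendered as a medium arrow with an explicit
#'   annotation).
#' * `quality` is one of `"high"`, `"moderate"`, `"low"` — exactly the three
#'   levels of the traffic-light row shading.
#'
#' Problems are returned, never raised, so a caller (or the command-line
#' front end) can report all of them at once. Studies that appear in some
#' domains but not others yield warnings, not errors: an incomplete grid is
#' legitimate and is drawn with explicit empty cells.
#'
#' @param outcomes data frame of outcome rows (one row per measured outcome).
#' @param studies data frame of study metadata (one row per study).
#' @return A tibble with columns `severity` (`"error"` or `"warning"`),
#'   `code`, and `message`, one row per problem; zero rows when the dataset
#'   is clean of errors and warnings.
#' @examples
#' ex <- housing_example()
#' validate_ed(ex$outcomes, ex$studies)
#' @export
validate_ed <- function(outcomes, studies) {
  issues <- list()
  add <- function(severity, code, message) {
    issues[[length(issues) + 1L]] <<- tibble(
      severity = severity, code = code, message = message
    )
  }

  need_out <- c("study_id", "domain_id", "outcome_name", "direction")
  need_stu <- c("study_id", "design", "n_intervention", "quality")
  miss_out <- setdiff(need_out, names(outcomes))
  miss_stu <- setdiff(need_stu, names(studies))
  for (m in miss_out) {
    add("error", "missing_column", paste0("outcomes: missing column '", m, "'"))
  }
  for (m in miss_stu) {
    add("error", "missing_column", paste0("studies: missing column '", m, "'"))
  }
  if (length(miss_out) || length(miss_stu)) {
    return(bind_rows(issues))
  }

  outcomes <- as_tibble(outcomes)
  studies <- as_tibble(studies)

  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  if (any(blank(outcomes$study_id)) || any(blank(outcomes$domain_id))) {
    add("error", "empty_identifier",
        "outcomes: study_id and domain_id must be non-empty")
  }

  bad_dir <- setdiff(unique(as.character(outcomes$direction)), ed_directions())
  for (d in bad_dir) {
    add("error", "invalid_direction",
        paste0("outcomes: direction '", d,
               "' is not one of positive/negative/no_change"))
  }

  dup <- outcomes |>
    count(.data$study_id, .data$domain_id, .data$outcome_name) |>
    filter(.data$n > 1L)
  for (i in seq_len(nrow(dup))) {
    add("error", "duplicate_outcome",
        paste0("outcomes: duplicate row for (", dup$study_id[i], ", ",
               dup$domain_id[i], ", ", dup$outcome_name[i], ")"))
  }

  dup_study <- studies |> count(.data$study_id) |> filter(.data$n > 1L)
  for (i in seq_len(nrow(dup_study))) {
    add("error", "duplicate_study",
        paste0("studies: study '", dup_study$study_id[i],
               "' has more than one metadata row"))
  }

  orphan <- setdiff(unique(outcomes$study_id), studies$study_id)
  for (s in orphan) {
    add("error", "unknown_study",
        paste0("outcomes: study '", s, "' has no matching study metadata"))
  }

  bad_q <- setdiff(unique(as.character(studies$quality)), ed_qualities())
  for (q in bad_q) {
    add("error", "invalid_quality",
        paste0("studies: quality '", q, "' is not one of high/moderate/low"))
  }

  n <- studies$n_intervention
  bad_n <- !is.na(n) & (n < 0 | n != floor(n))
  for (s in studies$study_id[bad_n]) {
    add("error", "invalid_sample_size",
        paste0("studies: n_intervention for '", s,
               "' must be a non-negative whole number or NA"))
  }

  # warnings: studies present in the review but absent from some domain
  if (nrow(outcomes) > 0L) {
    doms <- sort(unique(outcomes$domain_id))
    present <- outcomes |> distinct(.data$study_id, .data$domain_id)
    for (s in sort(unique(studies$study_id))) {
      absent <- setdiff(doms, present$domain_id[present$study_id == s])
      if (length(absent) && s %in% outcomes$study_id) {
        add("warning", "incomplete_grid",
            paste0("study '", s, "' has no outcomes in domain(s): ",
                   paste(absent, collapse = ", ")))
      }
    }
    unused <- setdiff(studies$study_id, outcomes$study_id)
    for (s in unused) {
      add("warning", "study_without_outcomes",
          paste0("study '", s, "' contributes no outcomes"))
    }
  }

  if (length(issues) == 0L) {
    return(tibble(severity = character(), code = character(),
                  message = character()))
  }
  bind_rows(issues)
}

# stop() with all validation errors when any are present; used by pipeline
# entry points so programmatic callers fail fast while validate_ed() itself
# never raises
assert_valid_ed <- function(outcomes, studies) {
  report <- validate_ed(outcomes, studies)
  errs <- report$message[report$severity == "error"]
  if (length(errs)) {
    stop("invalid effect direction dataset:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(report)
}
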