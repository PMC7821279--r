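#' Input dialect: formats, column names, direction vocabulary
#'
#' Describes how a long-format review table maps onto the package's
#' canonical columns. The input is one row per measured outcome, with the
#' study's metadata repeated on each of its rows; [read_ed_data()] splits it
#' into the outcomes and studies tables.
#'
#' The direction vocabulary is total over its declared tokens: any token not
#' listed (after trimming whitespace and lower-casing) is a read error, never
#' a silent coercion. The default vocabulary accepts
#' `positive/+/up/improved`, `negative/-/down/worsened`, and
#' `none/0/no change/no_change/null`; qualities accept
#' `high/moderate/low` plus `medium` as a synonym for moderate.
#'
#' @param format `"csv"`, `"tsv"`, or `"json"`.
#' @param columns named character vector mapping canonical names
#'   (`study_id`, `domain_id`, `outcome_name`, `direction`, `design`,
#'   `n_intervention`, `quality`) to the file's column names.
#' @param direction_vocabulary named list: elements `positive`, `negative`,
#'   `no_change`, each a character vector of accepted tokens
#'   (case-insensitive).
#' @param quality_vocabulary named list: elements `high`, `moderate`, `low`.
#' @return An `ed_dialect` list object.
#' @examples
#' d <- ed_dialect(format = "tsv")
#' d$format
#' @export
ed_dialect <- function(format = c("csv", "tsv", "json"),
                       columns = NULL,
                       direction_vocabulary = NULL,
                       quality_vocabulary = NULL) {
  format <- match.arg(format)
  default_cols <- c(
    study_id = "study_id", domain_id = "domain_id",
    outcome_name = "outcome_name", direction = "direction",
    design = "design", n_intervention = "n_intervention",
    quality = "quality"
  )
  if (!is.null(columns)) {
    default_cols[names(columns)] <- unname(columns)
  }
  dir_vocab <- list(
    positive = c("positive", "+", "up", "improved"),
    negative = c("negative", "-", "down", "worsened"),
    no_change = c("none", "0", "no change", "no_change", "null")
  )
  if (!is.null(direction_vocabulary)) {
    dir_vocab[names(direction_vocabulary)] <- direction_vocabulary
  }
  q_vocab <- list(
    high = "high", moderate = c("moderate", "medium"), low = "low"
  )
  if (!is.null(quality_vocabulary)) {
    q_vocab[names(quality_vocabulary)] <- quality_vocabulary
  }
  structure(
    list(format = format, columns = default_cols,
         direction_vocabulary = dir_vocab, quality_vocabulary = q_vocab),
    class = "ed_dialect"
  )
}

map_vocab <- function(tokens, vocab, what) {
  clean <- tolower(trimws(tokens))
  lookup <- unlist(lapply(names(vocab), function(lab) {
    setNames(rep(lab, length(vocab[[lab]])), tolower(vocab[[lab]]))
  }))
  mapped <- unname(lookup[clean])
  bad <- unique(tokens[is.na(mapped) & !is.na(tokens)])
  if (length(bad)) {
    stop("unmapped ", what, " token(s): ",
         paste0("'", bad, "'", collapse = ", "), call. = FALSE)
  }
  mapped
}

#' Read a long-format effect direction dataset
#'
#' Reads CSV/TSV (RFC 4180-style quoting, UTF-8) or JSON input, maps the
#' direction and quality vocabularies, splits the table into outcomes and
#' study metadata, and validates the result. JSON input may be either a flat
#' array of row objects (long format) or an object with `outcomes` and
#' `studies` arrays as written by [write_ed_data()].
#'
#' @param path input file.
#' @param dialect an [ed_dialect()].
#' @return List with `outcomes`, `studies`, and `validation` (the
#'   [validate_ed()] report). Errors in the report raise a condition listing
#'   all of them.
#' @examples
#' path <- system.file("extdata", "housing_example.csv", package = "edplot")
#' dat <- read_ed_data(path)
#' dat$studies
#' @export
read_ed_data <- function(path, dialect = ed_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (dialect$format == "json") {
    parsed <- jsonlite::fromJSON(path)
    if (is.data.frame(parsed)) {
      long <- as_tibble(parsed)
    } else if (all(c("outcomes", "studies") %in% names(parsed))) {
      outcomes <- as_tibble(parsed$outcomes)
      studies <- as_tibble(parsed$studies) |>
        mutate(n_intervention = as.integer(.data$n_intervention))
      assert_valid_ed(outcomes, studies)
      return(list(outcomes = outcomes, studies = studies,
                  validation = validate_ed(outcomes, studies)))
    } else {
      stop("unrecognized JSON layout: expected a row array or ",
           "{outcomes, studies}", call. = FALSE)
    }
  } else {
    delim <- if (dialect$format == "tsv") "\t" else ","
    long <- readr::read_delim(
      path, delim = delim, col_types = readr::cols(.default = "c"),
      trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
    )
  }

  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols), names(long))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  long <- long |>
    rename(!!!setNames(unname(cols), names(cols)))
  long[] <- lapply(long, function(x) if (is.character(x)) trimws(x) else x)

  outcomes <- long |>
    mutate(direction = map_vocab(.data$direction,
                                 dialect$direction_vocabulary,
                                 "direction")) |>
    select("study_id", "domain_id", "outcome_name", "direction")

  studies <- long |>
    mutate(
      quality = map_vocab(.data$quality, dialect$quality_vocabulary,
                          "quality"),
      n_intervention = suppressWarnings(
        as.integer(dplyr::na_if(as.character(.data$n_intervention), ""))
      )
    ) |>
    distinct(.data$study_id, .data$design, .data$n_intervention,
             .data$quality)

  inconsistent <- studies |> count(.data$study_id) |> filter(.data$n > 1L)
  if (nrow(inconsistent)) {
    stop("inconsistent study metadata across rows for: ",
         paste(inconsistent$study_id, collapse = ", "), call. = FALSE)
  }

  assert_valid_ed(outcomes, studies)
  list(outcomes = outcomes, studies = studies,
       validation = validate_ed(outcomes, studies))
}

#' Write an effect direction dataset
#'
#' Writes the canonical dataset back to disk. CSV/TSV output is the long
#' format read by [read_ed_data()] (one row per outcome, study metadata
#' repeated); JSON output is an object with separate `outcomes` and
#' `studies` arrays. Reading the written file reproduces the dataset exactly.
#'
#' @param outcomes,studies canonical tibbles.
#' @param path output file.
#' @param format `"csv"`, `"tsv"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_ed_data <- function(outcomes, studies, path,
                          format = c("csv", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(outcomes = outcomes, studies = studies),
      path, auto_unbox = FALSE, na = "null", digits = NA, pretty = TRUE
    )
  } else {
    long <- outcomes |> left_join(studies, by = "study_id")
    if (format == "csv") {
      readr::write_csv(long, path, na = "", progress = FALSE)
    } else {
      readr::write_tsv(long, path, na = "", progress = FALSE)
    }
  }
  invisible(path)
}

#' Write synthesis and sign-test results
#'
#' Exports the per-(study, domain) syntheses and the per-domain sign tests.
#' JSON output is a single object with `syntheses` and `sign_tests` arrays;
#' CSV output writes two files, `<stem>_syntheses.csv` and
#' `<stem>_sign_tests.csv` (the two tables have different grains). Sign-test
#' rows carry the full-precision p-value, the 4-decimal display form
#' (`.0039` style), and the caveat flags spelled out.
#'
#' @param syntheses tibble from [synthesize_directions()].
#' @param sign_tests tibble from [sign_test_domains()].
#' @param path output file (for CSV, the stem used for the two files).
#' @param format `"csv"` or `"json"`.
#' @return Character vector of the file path(s) written, invisibly.
#' @export
write_ed_results <- function(syntheses, sign_tests, path,
                             format = c("csv", "json")) {
  format <- match.arg(format)
  st_flat <- as_tibble(sign_tests) |>
    mutate(caveats = purrr::map_chr(.data$caveats, paste, collapse = ";"))
  if (format == "json") {
    jsonlite::write_json(
      list(syntheses = syntheses, sign_tests = st_flat),
      path, auto_unbox = FALSE, na = "null", digits = NA, pretty = TRUE
    )
    invisible(path)
  } else {
    stem <- sub("\\.csv$", "", path)
    p1 <- paste0(stem, "_syntheses.csv")
    p2 <- paste0(stem, "_sign_tests.csv")
    readr::write_csv(syntheses, p1, na = "", progress = FALSE)
    readr::write_csv(st_flat, p2, na = "", progress = FALSE)
    invisible(c(p1, p2))
  }
}

#' Read results written by [write_ed_results()]
#'
#' @param path the JSON file, or the CSV stem passed to
#'   [write_ed_results()].
#' @param format `"csv"` or `"json"`.
#' @return List with `syntheses` and `sign_tests` tibbles (caveats restored
#'   to a list-column).
#' @export
read_ed_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    parsed <- jsonlite::fromJSON(path)
    syntheses <- as_tibble(parsed$syntheses)
    sign_tests <- as_tibble(parsed$sign_tests)
  } else {
    stem <- sub("\\.csv$", "", path)
    syntheses <- readr::read_csv(paste0(stem, "_syntheses.csv"),
                                 show_col_types = FALSE, progress = FALSE)
    sign_tests <- readr::read_csv(paste0(stem, "_sign_tests.csv"),
                                  show_col_types = FALSE, progress = FALSE)
  }
  sign_tests <- sign_tests |>
    mutate(caveats = purrr::map(
      as.character(.data$caveats),
      function(x) if (is.na(x) || !nzchar(x)) character() else
        strsplit(x, ";", fixed = TRUE)[[1]]
    ))
  list(syntheses = syntheses, sign_tests = sign_tests)
}
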