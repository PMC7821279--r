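#' Exact two-tailed binomial sign test on direction counts
#'
#' Tests the null hypothesis that positive and negative study-level effect
#' directions are equally likely. With `n = n_positive + n_negative` eligible
#' studies and `k = max(n_positive, n_negative)`, the two-tailed p-value is
#'
#' \deqn{p = \min\left(1,\; 2 \sum_{i=k}^{n} \binom{n}{i} (1/2)^n\right)}
#'
#' i.e. the doubled upper tail, capped at 1. Because the null is symmetric at
#' 1/2, doubling coincides with summing both tails, and matches standard
#' exact-binomial calculators. For `n <= 50` the tail is accumulated as an
#' exact integer sum of binomial coefficients before the single division by
#' `2^n`; larger `n` (far beyond any realistic review) falls back to
#' [stats::pbinom()].
#'
#' Studies with an unclear/conflicting domain-level direction must be
#' excluded *before* calling this function — they represent neither a
#' positive nor a negative effect (see [count_directions()]).
#'
#' @param n_positive,n_negative non-negative integer vectors (recycled) of
#'   study-level direction counts; each pair must have `n_positive +
#'   n_negative >= 1`.
#' @return Numeric vector of two-tailed p-values in (0, 1].
#' @examples
#' exact_sign_test(9, 0)  # 0.00390625, displayed as .0039
#' exact_sign_test(5, 1)  # 0.21875,    displayed as .2188
#' @seealso [sign_test_domains()] for the per-domain wrapper with exclusion
#'   accounting and caveat flags; [format_p()] for display rounding.
#' @export
exact_sign_test <- function(n_positive, n_negative) {
  if (length(n_positive) != length(n_negative)) {
    pair <- vctrs_recycle2(n_positive, n_negative)
    n_positive <- pair[[1]]
    n_negative <- pair[[2]]
  }
  if (any(is.na(n_positive) | is.na(n_negative))) {
    stop("direction counts must not be NA", call. = FALSE)
  }
  if (any(n_positive < 0 | n_negative < 0)) {
    stop("direction counts must be non-negative", call. = FALSE)
  }
  if (any(n_positive + n_negative < 1)) {
    stop("no eligible studies: n_positive + n_negative must be >= 1",
         call. = FALSE)
  }
  mapply(function(a, b) {
    n <- a + b
    k <- max(a, b)
    if (n <= 50) {
      tail_sum <- sum(choose(n, k:n)) # exact integers up to n = 50
      p <- 2 * tail_sum / 2^n
    } else {
      p <- 2 * pbinom(k - 1, n, 0.5, lower.tail = FALSE)
    }
    min(1, p)
  }, as.integer(n_positive), as.integer(n_negative))
}

# minimal common-length recycling (scalar against vector)
vctrs_recycle2 <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) != n && length(a) != 1L || length(b) != n && length(b) != 1L) {
    stop("count vectors must have equal length or length 1", call. = FALSE)
  }
  list(rep_len(a, n), rep_len(b, n))
}

#' Tally study-level directions for one outcome domain
#'
#' Counts how many studies in a domain synthesized to a positive, negative,
#' or unclear direction. Unclear studies are excluded from the sign test (they
#' cannot be said to represent either direction) but are counted so the
#' exclusion fraction can be reported alongside the p-value.
#'
#' @param syntheses data frame of domain syntheses for a single domain (as
#'   produced by [synthesize_directions()]), at most one row per study.
#' @return One-row tibble: `n_positive_studies`, `n_negative_studies`,
#'   `n_excluded_unclear`, `n_total_studies`.
#' @export
count_directions <- function(syntheses) {
  syntheses <- as_tibble(syntheses)
  if (nrow(syntheses) > 0L) {
    if (length(unique(syntheses$domain_id)) > 1L) {
      stop("count_directions expects syntheses from a single domain",
           call. = FALSE)
    }
    if (anyDuplicated(syntheses$study_id)) {
      stop("more than one synthesis for the same study in one domain",
           call. = FALSE)
    }
  }
  d <- syntheses$direction
  tibble(
    n_positive_studies = sum(d == "positive"),
    n_negative_studies = sum(d == "negative"),
    n_excluded_unclear = sum(d == "unclear"),
    n_total_studies = length(d)
  )
}

#' Sign tests with exclusion accounting and interpretation caveats
#'
#' For each outcome domain, tallies study-level directions, excludes
#' unclear/conflicting studies, computes the exact two-tailed sign test
#' p-value, and attaches caveat flags that operationalize the method's known
#' weaknesses:
#'
#' * `no_eligible_studies` — every study was unclear; the p-value is
#'   undefined (`NA`).
#' * `high_exclusion_fraction` — more than `exclusion_threshold` (default
#'   1/2) of the domain's studies were excluded as unclear, so the test
#'   arguably misrepresents the synthesis (e.g. a 20-study domain with 11
#'   conflicting results tests only 9 of 20 studies).
#' * `small_k` — fewer than `small_k_threshold` (default 6) eligible studies:
#'   6 is the smallest count at which even a unanimous split can reach a
#'   two-tailed p below 0.05 (`2 * (1/2)^6 = 0.03125`).
#' * `publication_bias_unassessed` — set unless the caller asserts
#'   `publication_bias_assessed = TRUE`; the sign test should not be used
#'   when publication bias is suspected.
#'
#' The default thresholds for the first two heuristics are package choices,
#' not part of the synthesis algorithm, and are exposed as arguments.
#' Result objects deliberately carry no significant yes/no field; the print
#' method instead reminds users that patterns of effect direction should not
#' be described as statistically significant or not.
#'
#' @param syntheses tibble from [synthesize_directions()] (any number of
#'   domains).
#' @param publication_bias_assessed set `TRUE` only if publication bias was
#'   formally assessed for the review.
#' @param exclusion_threshold flag domains whose excluded fraction exceeds
#'   this value (default 0.5).
#' @param small_k_threshold flag domains with fewer eligible studies than
#'   this (default 6).
#' @return A tibble with one row per domain: the counts of
#'   [count_directions()], `p_two_tailed` (full precision; `NA` when no
#'   eligible studies), `p_display` (4 decimal places, no leading zero), and
#'   `caveats` (list-column of flag names).
#' @examples
#' ex <- housing_example()
#' ex$outcomes |>
#'   synthesize_directions(ex$studies) |>
#'   sign_test_domains()
#' @export
sign_test_domains <- function(syntheses, publication_bias_assessed = FALSE,
                              exclusion_threshold = 0.5,
                              small_k_threshold = 6L) {
  syntheses <- as_tibble(syntheses)
  doms <- unique(syntheses$domain_id)
  res <- purrr::map(doms, function(d) {
    counts <- count_directions(syntheses |> filter(.data$domain_id == d))
    k_eligible <- counts$n_positive_studies + counts$n_negative_studies
    p <- if (k_eligible >= 1L) {
      exact_sign_test(counts$n_positive_studies, counts$n_negative_studies)
    } else {
      NA_real_
    }
    flags <- character()
    if (k_eligible == 0L) flags <- c(flags, "no_eligible_studies")
    if (counts$n_total_studies > 0L &&
        counts$n_excluded_unclear / counts$n_total_studies >
          exclusion_threshold) {
      flags <- c(flags, "high_exclusion_fraction")
    }
    if (k_eligible > 0L && k_eligible < small_k_threshold) {
      flags <- c(flags, "small_k")
    }
    if (!publication_bias_assessed) {
      flags <- c(flags, "publication_bias_unassessed")
    }
    counts |>
      mutate(domain_id = d, p_two_tailed = p, p_display = format_p(p),
             caveats = list(flags)) |>
      select("domain_id", dplyr::everything())
  })
  bind_rows(res)
}

#' Display-format a p-value
#'
#' Rounds to four decimal places and drops the leading zero (`0.00390625`
#' becomes `".0039"`), the conventional style for reporting sign test
#' results. Full-precision values should be kept alongside.
#'
#' @param p numeric vector of p-values (`NA` allowed).
#' @return Character vector; `NA_character_` where `p` is `NA`.
#' @examples
#' format_p(exact_sign_test(5, 1))
#' @export
format_p <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
                sub("^0\\.", ".", sprintf("%.4f", p)))
  as.character(out)
}

# fixed interpretation note rendered by print methods and the CLI
ed_caveat_note <- function() {
  paste(
    "Note: describe patterns of effect direction without labelling them",
    "statistically significant or not; sign test p-values support, not",
    "replace, transparent narrative synthesis."
  )
}
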