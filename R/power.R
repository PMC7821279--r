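#' Simulate review-level direction counts
#'
#' Draws replicate synthetic reviews of `k_studies` independent studies.
#' Each study is unclear/conflicting with probability `p_unclear`; otherwise
#' it shows a positive domain-level direction with probability `p_positive`
#' and a negative one with probability `1 - p_positive`. This is the minimal
#' generative model behind the sign test's power problem: unclear studies are
#' excluded from the test, shrinking its effective sample.
#'
#' Reproducibility contract: all randomness comes from R's default
#' Mersenne-Twister generator seeded once with `seed`, so a scenario is fully
#' determined by its parameters plus the seed.
#'
#' @param k_studies number of studies in the review.
#' @param p_positive probability a non-unclear study is positive.
#' @param p_unclear probability a study is unclear (excluded from the test).
#' @param replicates number of simulated reviews.
#' @param seed integer seed.
#' @return Tibble with one row per replicate: `n_pos`, `n_neg`, `n_unclear`.
#' @examples
#' simulate_reviews(k_studies = 10, p_positive = 0.8, p_unclear = 0.2,
#'                  replicates = 5, seed = 1)
#' @export
simulate_reviews <- function(k_studies, p_positive, p_unclear = 0,
                             replicates = 1000L, seed = 1L) {
  stopifnot(
    k_studies >= 1, replicates >= 1,
    p_positive >= 0, p_positive <= 1,
    p_unclear >= 0, p_unclear < 1
  )
  set.seed(as.integer(seed))
  n_unclear <- rbinom(replicates, k_studies, p_unclear)
  n_pos <- rbinom(replicates, k_studies - n_unclear, p_positive)
  tibble(
    n_pos = n_pos,
    n_neg = k_studies - n_unclear - n_pos,
    n_unclear = n_unclear
  )
}

#' Monte-Carlo power of the sign test for a review scenario
#'
#' Estimates, for each scenario row, the probability that the per-domain
#' sign test rejects at level `alpha` — together with the mean number of
#' eligible (non-unclear) studies and the fraction of replicates in which no
#' study at all was eligible (p-value undefined). Under the null
#' (`p_positive = 0.5`, `p_unclear = 0`) the rejection rate estimates the
#' test's actual type-I error, which the discreteness of small counts keeps
#' well below `alpha`; with `p_positive` near 1 it estimates power.
#'
#' Arguments are vectorized over scenarios (recycled to a common grid with
#' `tidyr::expand_grid` semantics left to the caller: pass equal-length
#' vectors or scalars). A Monte-Carlo standard error for the rejection rate
#' is reported alongside each estimate; results are suitable for direct
#' export with [readr::write_csv()].
#'
#' @inheritParams simulate_reviews
#' @param alpha rejection threshold (default 0.05).
#' @param seed integer seed; scenario `i` uses `seed + i - 1` so scenarios
#'   are independently reproducible.
#' @return Tibble with one row per scenario: the scenario parameters,
#'   `rejection_rate`, `mc_se`, `mean_eligible`, `undefined_rate`, and
#'   `replicates`.
#' @examples
#' # a unanimous 5-study review can never reject at alpha = 0.05,
#' # a unanimous 6-study review always does
#' estimate_power(k_studies = c(5, 6), p_positive = 1, p_unclear = 0,
#'                replicates = 200, seed = 1)
#' @export
estimate_power <- function(k_studies, p_positive, p_unclear = 0,
                           alpha = 0.05, replicates = 10000L, seed = 1L) {
  grid <- tibble(
    k_studies = k_studies,
    p_positive = p_positive,
    p_unclear = p_unclear,
    alpha = alpha
  )
  purrr::pmap(
    c(grid, list(.i = seq_len(nrow(grid)))),
    function(k_studies, p_positive, p_unclear, alpha, .i) {
      sims <- simulate_reviews(k_studies, p_positive, p_unclear,
                               replicates = replicates,
                               seed = as.integer(seed) + .i - 1L)
      eligible <- sims$n_pos + sims$n_neg
      defined <- eligible >= 1L
      p <- rep(NA_real_, nrow(sims))
      p[defined] <- exact_sign_test(sims$n_pos[defined], sims$n_neg[defined])
      reject <- !is.na(p) & p <= alpha
      rate <- mean(reject)
      tibble(
        k_studies = k_studies, p_positive = p_positive,
        p_unclear = p_unclear, alpha = alpha,
        rejection_rate = rate,
        mc_se = sqrt(rate * (1 - rate) / replicates),
        mean_eligible = mean(eligible),
        undefined_rate = mean(!defined),
        replicates = as.integer(replicates)
      )
    }
  ) |>
    bind_rows()
}

#' Exact rejection rate of the sign test by enumeration
#'
#' Closed-form companion to [estimate_power()] for the no-unclear case:
#' enumerates the binomial distribution of positive counts and sums the
#' probability of counts whose two-tailed sign test p-value is at or below
#' `alpha`. Used to calibrate the Monte-Carlo estimate.
#'
#' @inheritParams estimate_power
#' @return Numeric vector of exact rejection probabilities.
#' @examples
#' exact_rejection_rate(10, 0.5)      # 2 * P(Bin(10, 1/2) >= 9)
#' exact_rejection_rate(6, 1)         # 1: unanimous 6/6 has p = 0.03125
#' @export
exact_rejection_rate <- function(k_studies, p_positive, alpha = 0.05) {
  mapply(function(k, pp) {
    counts <- 0:k
    pvals <- exact_sign_test(counts, k - counts)
    sum(stats::dbinom(counts, k, pp)[pvals <= alpha])
  }, k_studies, p_positive)
}
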