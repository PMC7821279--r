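test_that("exact_sign_test reproduces the worked-example p-values", {
  expect_identical(exact_sign_test(9, 0), 0.00390625)
  expect_identical(exact_sign_test(5, 1), 0.21875)
  expect_identical(exact_sign_test(1, 1), 1)
  expect_identical(exact_sign_test(8, 1), 0.0390625)
  expect_equal(format_p(c(0.00390625, 0.21875, NA)),
               c(".0039", ".2188", NA_character_))
})

test_that("exact_sign_test validates its inputs", {
  expect_error(exact_sign_test(0, 0), "eligible")
  expect_error(exact_sign_test(-1, 2), "non-negative")
  expect_error(exact_sign_test(NA, 2), "NA")
})

test_that("exact_sign_test is symmetric and unanimous votes have closed form", {
  for (a in 0:8) {
    for (b in 0:8) {
      if (a + b == 0) next
      expect_identical(exact_sign_test(a, b), exact_sign_test(b, a))
    }
  }
  for (n in 1:20) {
    expect_equal(exact_sign_test(n, 0), min(1, 2 * 0.5^n))
  }
})

test_that("exact_sign_test matches the exact binomial test for all pairs up to 25", {
  # independent oracle: stats::binom.test; its two-sided rule coincides with
  # doubling the larger tail because the null at 1/2 is symmetric
  for (n in 1:25) {
    for (a in 0:n) {
      expect_equal(exact_sign_test(a, n - a),
                   stats::binom.test(a, n, 0.5)$p.value,
                   tolerance = 1e-12, label = paste0("(", a, ",", n - a, ")"))
    }
  }
})

test_that("for fixed total, p never increases as the split grows more lopsided", {
  for (n in c(5, 10, 17)) {
    p <- exact_sign_test(seq(ceiling(n / 2), n), n - seq(ceiling(n / 2), n))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("count_directions tallies and excludes per the method", {
  syn <- tibble::tibble(
    study_id = sprintf("S%02d", 1:10),
    domain_id = "dom",
    direction = rep(c("positive", "unclear"), c(9, 1))
  )
  expect_equal(
    count_directions(syn),
    tibble::tibble(n_positive_studies = 9L, n_negative_studies = 0L,
                   n_excluded_unclear = 1L, n_total_studies = 10L)
  )
  mixed <- tibble::tibble(
    study_id = sprintf("S%02d", 1:10), domain_id = "dom",
    direction = rep(c("positive", "negative", "unclear"), c(5, 1, 4))
  )
  cts <- count_directions(mixed)
  expect_equal(cts$n_positive_studies, 5L)
  expect_equal(cts$n_negative_studies, 1L)
  expect_equal(cts$n_excluded_unclear, 4L)
  expect_equal(
    cts$n_positive_studies + cts$n_negative_studies + cts$n_excluded_unclear,
    cts$n_total_studies
  )
  expect_equal(count_directions(syn[0, ])$n_total_studies, 0L)
  expect_error(count_directions(dplyr::bind_rows(syn, syn[1, ])),
               "same study")
  expect_error(
    count_directions(syn |> dplyr::mutate(domain_id = c("a", rep("dom", 9)))),
    "single domain"
  )
})

test_that("sign_test_domains attaches p-values and caveat flags", {
  mk_syn <- function(n_pos, n_neg, n_unc, domain = "dom") {
    tibble::tibble(
      study_id = sprintf("S%02d", seq_len(n_pos + n_neg + n_unc)),
      domain_id = domain,
      direction = rep(c("positive", "negative", "unclear"),
                      c(n_pos, n_neg, n_unc))
    )
  }
  res <- sign_test_domains(mk_syn(9, 0, 1))
  expect_equal(res$p_two_tailed, 0.00390625)
  expect_equal(res$p_display, ".0039")
  expect_false("high_exclusion_fraction" %in% res$caveats[[1]])
  expect_false("small_k" %in% res$caveats[[1]])
  expect_true("publication_bias_unassessed" %in% res$caveats[[1]])

  # hypothetical 20-study domain with 11 conflicting: test covers only 9/20
  res <- sign_test_domains(mk_syn(8, 1, 11))
  expect_equal(res$p_two_tailed, 0.0390625)
  expect_true("high_exclusion_fraction" %in% res$caveats[[1]])

  res <- sign_test_domains(mk_syn(0, 0, 3))
  expect_true(is.na(res$p_two_tailed))
  expect_true("no_eligible_studies" %in% res$caveats[[1]])

  res <- sign_test_domains(mk_syn(4, 1, 0))
  expect_true("small_k" %in% res$caveats[[1]])
  res <- sign_test_domains(mk_syn(5, 1, 0))
  expect_false("small_k" %in% res$caveats[[1]])

  res <- sign_test_domains(mk_syn(5, 1, 0), publication_bias_assessed = TRUE)
  expect_false("publication_bias_unassessed" %in% res$caveats[[1]])

  # bookkeeping identity holds per domain
  multi <- dplyr::bind_rows(mk_syn(3, 2, 1, "a"), mk_syn(0, 0, 2, "b"))
  res <- sign_test_domains(multi)
  expect_equal(res$n_positive_studies + res$n_negative_studies +
                 res$n_excluded_unclear, res$n_total_studies)
})

test_that("results expose no significance verdict field", {
  rev <- housing_example()
  fit <- effdir(rev$outcomes, rev$studies)
  expect_false(any(grepl("significan", names(fit$sign_tests))))
  expect_output(print(fit), "without labelling them statistically significant")
})
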