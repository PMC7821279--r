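test_that("synthesize_domain applies the 70% majority rule", {
  expect_equal(synthesize_domain(rep("positive", 3))$direction, "positive")
  expect_equal(synthesize_domain(rep("positive", 3))$majority_fraction, 1)

  # 7 of 10 meets the threshold inclusively; 6 of 10 does not
  expect_equal(
    synthesize_domain(rep(c("positive", "negative"), c(7, 3)))$direction,
    "positive"
  )
  expect_equal(
    synthesize_domain(rep(c("positive", "negative"), c(6, 4)))$direction,
    "unclear"
  )
  expect_equal(
    synthesize_domain(rep(c("negative", "positive"), c(7, 3)))$direction,
    "negative"
  )

  # no_change outcomes dilute under the default all-outcomes denominator
  s <- synthesize_domain(c("positive", "positive", "no_change"))
  expect_equal(s$direction, "unclear")
  expect_equal(s$majority_fraction, 2 / 3)

  # counts always partition the outcomes
  expect_equal(s$n_positive + s$n_negative + s$n_no_change, s$n_outcomes)

  expect_error(synthesize_domain(character()), "no outcomes")
  expect_error(synthesize_domain("sideways"), "invalid raw direction")
})

test_that("the directional denominator ignores no_change outcomes", {
  dirs <- c("positive", "positive", "no_change")
  expect_equal(synthesize_domain(dirs, denominator = "directional")$direction,
               "positive")
  # all-no_change has an empty directional denominator
  expect_equal(
    synthesize_domain(rep("no_change", 3),
                      denominator = "directional")$direction,
    "unclear"
  )
  expect_equal(synthesize_domain(rep("no_change", 3))$direction, "unclear")
})

test_that("synthesized direction matches the threshold rule for all small multisets", {
  # independent oracle: evaluate the 70% rule from the raw counts; no count
  # ratio with n <= 8 outcomes can tie 0.7 exactly, so the floating
  # comparison is unambiguous here (the integer boundary case is asserted
  # separately above with 7 of 10)
  oracle <- function(dirs) {
    np <- sum(dirs == "positive")
    nn <- sum(dirs == "negative")
    n <- length(dirs)
    if (np / n >= 0.7) "positive" else if (nn / n >= 0.7) "negative"
    else "unclear"
  }
  for (n in 1:8) {
    for (dirs in direction_multisets(n)) {
      expect_equal(synthesize_domain(dirs)$direction, oracle(dirs),
                   label = paste(dirs, collapse = ","))
    }
  }
})

test_that("synthesize_domain is permutation-invariant and exhaustive", {
  set.seed(7)
  for (i in 1:25) {
    dirs <- sample(ed_directions(), sample(1:8, 1), replace = TRUE)
    base <- synthesize_domain(dirs)
    expect_identical(synthesize_domain(sample(dirs)), base)
    expect_true(base$direction %in% c("positive", "negative", "unclear"))
  }
})

test_that("flipping outcomes toward positive never demotes a positive result", {
  checked <- 0L
  for (n in 2:8) {
    for (dirs in direction_multisets(n)) {
      if (synthesize_domain(dirs)$direction != "positive") next
      idx <- which(dirs != "positive")
      for (i in idx) {
        flipped <- replace(dirs, i, "positive")
        expect_equal(synthesize_domain(flipped)$direction, "positive")
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 0L)
})

test_that("arrow size classes follow the sample-size legend", {
  expect_equal(arrow_size_class(c(301, 300, 50, 49)),
               c("large", "medium", "medium", "small"))
  expect_equal(arrow_size_class(0), "small")
  expect_equal(arrow_size_class(NA), "medium")
  expect_error(arrow_size_class(-1), "non-negative")
})

test_that("synthesize_directions groups by study and domain, order-invariantly", {
  rev <- tiny_review()
  syn <- synthesize_directions(rev$outcomes, rev$studies)
  expect_equal(nrow(syn), 2L)
  expect_equal(syn$direction, c("positive", "negative"))
  expect_equal(syn$size_class, c("medium", "large"))
  expect_true(all(syn$n_known))

  # shuffled input yields the same per-group results
  shuffled <- rev$outcomes[c(3, 1, 4, 2), ]
  syn2 <- synthesize_directions(shuffled, rev$studies) |>
    dplyr::arrange(study_id, domain_id)
  expect_equal(syn2, syn |> dplyr::arrange(study_id, domain_id))

  # a study with three domains A, A, B partitions correctly
  out3 <- tibble::tibble(
    study_id = "S1", domain_id = c("A", "A", "B"),
    outcome_name = c("o1", "o2", "o1"), direction = "positive"
  )
  syn3 <- synthesize_directions(out3)
  expect_equal(syn3$n_outcomes, c(2L, 1L))

  expect_error(synthesize_directions(rev$outcomes[0, ]), "no outcomes")
})

test_that("unknown sample size synthesizes as medium with n_known = FALSE", {
  rev <- tiny_review()
  rev$studies$n_intervention[1] <- NA
  syn <- synthesize_directions(rev$outcomes, rev$studies)
  expect_equal(syn$size_class[syn$study_id == "S1"], "medium")
  expect_false(syn$n_known[syn$study_id == "S1"])
})
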