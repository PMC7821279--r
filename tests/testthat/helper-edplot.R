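# small hand-built review used across tests: 2 studies, 1 domain
tiny_review <- function() {
  list(
    outcomes = tibble::tibble(
      study_id = c("S1", "S1", "S2", "S2"),
      domain_id = "dom",
      outcome_name = c("o1", "o2", "o1", "o2"),
      direction = c("positive", "positive", "negative", "negative")
    ),
    studies = tibble::tibble(
      study_id = c("S1", "S2"),
      design = "RCT",
      n_intervention = c(100L, 400L),
      quality = c("high", "low")
    )
  )
}

# all multisets of raw direction labels with the given total count
direction_multisets <- function(n) {
  out <- list()
  for (n_pos in 0:n) {
    for (n_neg in 0:(n - n_pos)) {
      out[[length(out) + 1L]] <- c(
        rep("positive", n_pos), rep("negative", n_neg),
        rep("no_change", n - n_pos - n_neg)
      )
    }
  }
  out
}
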