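# A miniature population small enough for exhaustive enumeration.
mini_config <- function(roving_fraction = 1, ...) {
  field_config(n_pairs = 2, tiles_per_pair = 10, territory_tiles = 4,
               roving_fraction = roving_fraction, ...)
}

# All four coherent mechanics combinations (closed_form equals explicit in
# distribution and is checked separately).
mechanics_grid <- function() {
  list(mechanics_options("per_territory_minus40", shared_depletion = TRUE),
       mechanics_options("per_territory_minus40", shared_depletion = FALSE),
       mechanics_options("per_attempt_minus1", shared_depletion = TRUE),
       mechanics_options("per_attempt_minus1", shared_depletion = FALSE))
}

expect_within_3se <- function(sample_values, exact, label = "") {
  se <- stats::sd(sample_values) / sqrt(length(sample_values))
  expect_lt(abs(mean(sample_values) - exact), 3 * se + 1e-12,
            label = paste0(label, " |mean - exact|"))
}
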