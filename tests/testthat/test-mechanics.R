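test_that("mechanics_options validates and fingerprints", {
  m <- mechanics_options()
  expect_identical(m$depletion, "per_territory_minus40")
  expect_identical(m$rival_mode, "explicit")
  expect_true(m$shared_depletion)
  expect_identical(mechanics_fingerprint(m),
                   "per_territory_minus40/explicit/shared")
  expect_identical(
    mechanics_fingerprint(mechanics_options("per_attempt_minus1",
                                            shared_depletion = FALSE)),
    "per_attempt_minus1/explicit/independent")
  # a shared pool cannot be integrated out rival-by-rival
  expect_error(mechanics_options(rival_mode = "closed_form",
                                 shared_depletion = TRUE))
})

test_that("attempt probabilities follow the tile-exclusion sequence", {
  expect_equal(attempt_probability(1, 600, 160), 160 / 599)
  expect_equal(attempt_probability(2, 600, 160), 159 / 598)
  expect_equal(attempt_probability(3, 600, 160), 158 / 597)
  # TU exhausted -> probability floors at zero
  expect_equal(attempt_probability(3, 600, 1), 0)
  expect_error(attempt_probability(1, 600, 600), "unguarded")
  expect_error(attempt_probability(1, 600, 160, "per_territory_minus40"))
})

test_that("closed-form expected EPCs equals the sum of attempt probabilities", {
  expect_equal(expected_epc_per_foray(600, 160),
               160 / 599 + 159 / 598 + 158 / 597)
  expect_error(expected_epc_per_foray(600, 160,
                                      depletion = "per_territory_minus40"))
})
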