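test_that("enumeration mass is exactly 1 in every mechanics mode", {
  cfg <- mini_config(wanderer_fraction = 0.5, balanced_sex_ratio = TRUE)
  for (m in mechanics_grid()) {
    en <- enumerate_run(cfg, mechanics = m)
    expect_equal(en$mass, 1, tolerance = 1e-12,
                 label = mechanics_fingerprint(m))
    expect_equal(sum(en$pmf_R), 1, tolerance = 1e-12)
  }
})

test_that("engine means match exhaustive enumeration on miniatures", {
  cfg <- mini_config()
  for (m in mechanics_grid()) {
    en <- enumerate_run(cfg, mechanics = m)
    sim <- simulate_runs(cfg, n = 1e5, mechanics = m, seed = 17)
    lab <- mechanics_fingerprint(m)
    expect_within_3se(sim$E, en$E, paste(lab, "E"))
    expect_within_3se(sim$C, en$C, paste(lab, "C"))
    expect_within_3se(sim$R, en$R, paste(lab, "R"))
  }
})

test_that("enumeration handles wanderers and unpaired females", {
  cfg <- mini_config(wanderer_fraction = 0.5, balanced_sex_ratio = TRUE)
  for (m in mechanics_grid()) {
    en <- enumerate_run(cfg, mechanics = m)
    sim <- simulate_runs(cfg, n = 1e5, mechanics = m, seed = 23)
    expect_within_3se(sim$R, en$R, mechanics_fingerprint(m))
  }
})

test_that("degenerate fields enumerate to point masses", {
  # every attempt must succeed: TU = T - 1, no rivals
  f <- manual_field(121, 40, n_unpaired_females = 3)
  en <- enumerate_run(f)
  expect_equal(unname(en$pmf_R["16"]), 1, tolerance = 1e-12)
  # the lone wanderer must find the focal female: T - 1 = her territory
  f0 <- manual_field(41, 40, n_wanderers = 1)
  en0 <- enumerate_run(f0, mechanics_options(shared_depletion = FALSE))
  expect_equal(unname(en0$pmf_R["0"]), 1, tolerance = 1e-12)
})

test_that("the state-space guard refuses oversized enumerations", {
  big <- field_config(n_pairs = 50, roving_fraction = 1)
  expect_error(enumerate_run(big, max_paths = 1e5))
})

test_that("per-foray focal expectation matches the closed form (minus-1)", {
  f <- manual_field(600, 40, n_unpaired_females = 4)  # TU = 160
  m <- mechanics_options("per_attempt_minus1", shared_depletion = FALSE)
  P <- enumerate_foray(f, m)
  expect_equal(sum(0:3 * rowSums(P)), expected_epc_per_foray(600, 160),
               tolerance = 1e-12)
})
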