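test_that("the engine stream is deterministic in its seed", {
  cfg <- mini_config()
  a <- simulate_runs(cfg, n = 500, seed = 42)
  b <- simulate_runs(cfg, n = 500, seed = 42)
  d <- simulate_runs(cfg, n = 500, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("a NULL seed draws one from the session RNG", {
  cfg <- mini_config()
  set.seed(7)
  a <- simulate_runs(cfg, n = 100)
  set.seed(7)
  b <- simulate_runs(cfg, n = 100)
  expect_identical(a, b)
})

test_that("copulation_search counts EPCs within one search", {
  f <- build_field(field_config(n_pairs = 100, roving_fraction = 1))
  e <- copulation_search(f, n = 2000, seed = 1)
  expect_true(all(e >= 0 & e <= f$config$attempts_per_foray))
  expect_gt(mean(e), 0)
})

test_that("cuckold_check is 0/1 per foray and requires a roving focal male", {
  f <- build_field(field_config(n_pairs = 100, roving_fraction = 1))
  cc <- cuckold_check(field_for_foray(f, focal_roving = TRUE),
                      n = 2000, seed = 2)
  expect_true(all(cc %in% 0:1))
  expect_gt(mean(cc), 0)
  expect_error(cuckold_check(field_for_foray(f, focal_roving = FALSE)),
               "roves")
})

test_that("R always equals E + I - C with I = forays", {
  for (m in mechanics_grid()) {
    runs <- simulate_runs(mini_config(wanderer_fraction = 0.5,
                                      balanced_sex_ratio = TRUE),
                          n = 2000, mechanics = m, seed = 5)
    expect_identical(runs$R, runs$E + runs$I - runs$C)
    expect_true(all(runs$I == 4L))
    expect_true(all(runs$E >= 0 & runs$E <= 12))
    expect_true(all(runs$C >= 0 & runs$C <= 4))
  }
})

test_that("closed-form rival mode matches explicit rivals in distribution", {
  cfg <- field_config(n_pairs = 5, tiles_per_pair = 10, territory_tiles = 4,
                      roving_fraction = 1)
  exact <- enumerate_run(cfg, mechanics_options("per_attempt_minus1",
                                                shared_depletion = FALSE))
  draws <- simulate_runs(cfg, n = 1e5,
                         mechanics = mechanics_options(
                           "per_attempt_minus1", "closed_form",
                           shared_depletion = FALSE),
                         seed = 9)
  expect_within_3se(draws$C, exact$C, "closed-form C")
  expect_within_3se(draws$E, exact$E, "closed-form E")
})
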