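test_that("derived seeds are valid and collision-free across a sweep", {
  grid <- expand.grid(cond = 1:3, pct = seq(0, 100, by = 10), rep = 0:4)
  seeds <- mapply(derive_seed, 42, grid$cond, grid$pct, grid$rep)
  expect_identical(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 1))
  expect_error(derive_seed(1, 30, 0), "condition_id")
})

test_that("sweep_spec validates and warns on unstable replicate counts", {
  expect_warning(sweep_spec(condition1(n_pairs = 10), replicates = 50,
                            seed = 1),
                 "1000")
  expect_error(sweep_spec(condition1(), roving_grid = c(0, 1.5)))
  s <- sweep_spec(condition1(n_pairs = 10), replicates = 1000, seed = 1)
  expect_s3_class(s, "sweep_spec")
})

test_that("run_sweep aggregates cells with tests, FDR and provenance", {
  spec <- suppressWarnings(
    sweep_spec(condition1(n_pairs = 20), roving_grid = c(0, 0.5, 1),
               replicates = 400, seed = 3))
  out <- run_sweep(spec)
  expect_identical(nrow(out), 3L)
  expect_true(all(c("mean_R", "se_R", "mean_E", "mean_C", "ipc_component",
                    "epc_component", "p_raw", "p_fdr", "significant",
                    "undefined_test", "master_seed", "mechanics")
                  %in% names(out)))
  # the 0%-roving cell is deterministic, hence flagged undefined
  expect_true(out$undefined_test[out$roving_pct == 0])
  expect_true(is.na(out$p_fdr[out$roving_pct == 0]))
  ok <- !out$undefined_test
  expect_true(all(out$p_fdr[ok] >= out$p_raw[ok]))
  expect_identical(unique(out$mechanics),
                   "per_territory_minus40/explicit/shared")
  # components decompose the payoff
  expect_equal(out$mean_R, out$epc_component + out$ipc_component,
               tolerance = 1e-12)
})

test_that("sweeps are reproducible from the master seed alone", {
  spec <- suppressWarnings(
    sweep_spec(condition2(n_pairs = 20, wanderer_fraction = 0.2),
               roving_grid = c(0.3, 0.8), replicates = 300, seed = 11))
  expect_identical(run_sweep(spec), run_sweep(spec))
})
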