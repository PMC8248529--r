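test_that("one-sample t against the baseline matches hand computation", {
  tt <- ttest_vs_baseline(c(5, 6, 7), baseline = 4)
  # mean 6, sd 1, n 3: t = (6 - 4) / (1 / sqrt(3)) = sqrt(12); with df = 2
  # the two-tailed p has the closed form 1 - 2 * sqrt(3 / 14)
  expect_equal(tt$t, sqrt(12), tolerance = 1e-10)
  expect_identical(tt$df, 2L)
  expect_equal(tt$p, 1 - 2 * sqrt(3 / 14), tolerance = 1e-10)
  expect_false(tt$undefined)
  expect_error(ttest_vs_baseline(4), "two")
})

test_that("zero-variance samples yield a flagged undefined test", {
  tt <- ttest_vs_baseline(rep(4, 100))
  expect_true(tt$undefined)
  expect_true(is.na(tt$t))
  expect_true(is.na(tt$p))
  expect_equal(tt$mean, 4)
  expect_output(print(tt), "undefined")
})

test_that("BH-FDR matches the hand-worked example and never shrinks p", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.03)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("histogram summaries report shape and handle constant input", {
  set.seed(1)
  h <- histogram_summary(rnorm(5000), n_bins = 20)
  expect_equal(sum(h$counts), 5000)
  expect_lt(abs(h$skewness), 0.3)
  expect_lt(abs(h$kurtosis), 0.5)
  hc <- histogram_summary(rep(4, 10))
  expect_identical(hc$counts, 10L)
  expect_true(is.na(hc$skewness))
})

test_that("find_crossover interpolates linearly and returns NA without one", {
  cells <- data.frame(roving_pct = c(50, 60),
                      epc_component = c(1.5, 2.5),
                      ipc_component = c(2.0, 2.0))
  expect_equal(find_crossover(cells), 55)
  # exact tie at a grid point
  tie <- data.frame(roving_pct = c(40, 50), epc_component = c(2, 3),
                    ipc_component = c(2, 2))
  expect_equal(find_crossover(tie), 40)
  none <- data.frame(roving_pct = c(10, 50, 100),
                     epc_component = c(0.1, 0.4, 0.9),
                     ipc_component = c(3.9, 3.0, 2.1))
  expect_true(is.na(find_crossover(none)))
})
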