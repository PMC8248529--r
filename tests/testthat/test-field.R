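test_that("round_half_up rounds .5 upward, unlike round-half-even", {
  expect_identical(round_half_up(c(0.5, 1.5, 2.5, 499.5)),
                   c(1L, 2L, 3L, 500L))
  expect_identical(round_half_up(c(0, 1, 2.4, 2.6)), c(0L, 1L, 2L, 3L))
})

test_that("field_config validates its inputs", {
  expect_error(field_config(n_pairs = 1), "n_pairs")
  expect_error(field_config(roving_fraction = 1.2), "roving_fraction")
  expect_error(field_config(wanderer_fraction = -0.1), "wanderer_fraction")
  expect_error(field_config(territory_tiles = 150, tiles_per_pair = 100),
               "territory_tiles")
  expect_error(field_config(forays = 0), "forays")
  expect_s3_class(field_config(), "field_config")
})

test_that("build_field lays out tiles, territories and tactics", {
  f <- build_field(field_config(n_pairs = 1000, roving_fraction = 0.5))
  expect_equal(f$total_tiles, 100000)
  # 50% of the 999 non-focal males rove, rounded half-up
  expect_identical(f$n_rovers, 500L)
  expect_identical(f$n_true_residents, 499L)
  expect_equal(f$unguarded_tiles, 500 * 40)
  expect_identical(f$n_rival_seekers, 500L)
  expect_identical(f$focal_female_tiles, 40L)
})

test_that("wanderers add seekers; matched females add unguarded tiles", {
  c2 <- build_field(condition2(n_pairs = 1000, roving_fraction = 1,
                               wanderer_fraction = 0.4))
  expect_identical(c2$n_wanderers, 400L)
  expect_identical(c2$n_unpaired_females, 0L)
  expect_identical(c2$n_rival_seekers, 999L + 400L)
  expect_equal(c2$total_tiles, 100000)
  expect_equal(c2$unguarded_tiles, 999 * 40)

  c3 <- build_field(condition3(n_pairs = 1000, roving_fraction = 1,
                               wanderer_fraction = 0.4))
  expect_identical(c3$n_unpaired_females, 400L)
  # each unpaired female adds an unguarded territory and keeps density
  # constant by adding her share of habitat
  expect_equal(c3$unguarded_tiles, (999 + 400) * 40)
  expect_equal(c3$total_tiles, 100000 + 400 * 100)

  c3b <- build_field(condition3(n_pairs = 1000, roving_fraction = 1,
                                wanderer_fraction = 0.4,
                                unpaired_female_tiles_added = FALSE))
  expect_equal(c3b$total_tiles, 100000)
})

test_that("condition builders map onto condition ids", {
  expect_identical(condition_id(condition1()), 1L)
  expect_identical(condition_id(condition2(wanderer_fraction = 0.4)), 2L)
  expect_identical(condition_id(condition3(wanderer_fraction = 0.1)), 3L)
})

test_that("manual_field builds degenerate geometries and guards TU", {
  f <- manual_field(121, 40, n_unpaired_females = 3)
  expect_equal(f$unguarded_tiles, 120)
  expect_equal(f$total_tiles, 121)
  expect_error(manual_field(120, 40, n_unpaired_females = 3),
               "total_tiles - 1")
})

test_that("foray views carry the focal-roving flag", {
  f <- build_field(field_config(n_pairs = 10))
  v <- field_for_foray(f, focal_roving = FALSE)
  expect_s3_class(v, "foray_view")
  expect_false(v$focal_roving)
  expect_true(field_for_foray(f)$focal_roving)
})
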