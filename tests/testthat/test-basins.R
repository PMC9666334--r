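grid21 <- seq(0, 100, length.out = 21)

test_that("the monostable regime has a single all-zero basin", {
  bg <- map_basins(loop_params(a = 1), T_init = 80,
                   s_grid = grid21, v_grid = grid21)
  expect_true(all(bg$label == "zero"))
  expect_equal(basin_area_fraction(bg, "high"), 0)
  expect_equal(basin_area_fraction(bg, "zero"), 1)
})

test_that("just below the fold both basins are non-empty and partition the grid", {
  bg <- map_basins(loop_params(a = 0.26), T_init = 80,
                   s_grid = grid21, v_grid = grid21)
  fr <- attr(bg, "fractions")
  expect_gt(basin_area_fraction(bg, "zero"), 0)
  expect_gt(basin_area_fraction(bg, "high"), 0)
  expect_equal(sum(fr), 1)
  # the baseline corner starts in the zero basin
  expect_identical(bg$label[bg$S0 == 0 & bg$V0 == 0], "zero")
})

test_that("the high-firing basin grows as the efficacy decreases", {
  grid41 <- seq(0, 100, length.out = 41)
  frac <- vapply(c(0.25, 0.20, 0.15), function(a) {
    basin_area_fraction(
      map_basins(loop_params(a = a), T_init = 80,
                 s_grid = grid41, v_grid = grid41), "high")
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("area fractions are stable under grid refinement", {
  grid51 <- seq(0, 100, length.out = 51)
  grid101 <- seq(0, 100, length.out = 101)
  f1 <- basin_area_fraction(
    map_basins(loop_params(a = 0.2), T_init = 80,
               s_grid = grid51, v_grid = grid51), "high")
  f2 <- basin_area_fraction(
    map_basins(loop_params(a = 0.2), T_init = 80,
               s_grid = grid101, v_grid = grid101), "high")
  expect_lt(abs(f1 - f2), 0.02)
})

test_that("the reversed-GABA variant has a high basin at least as wide", {
  grid31 <- seq(0, 100, length.out = 31)
  f_std <- basin_area_fraction(
    map_basins(loop_params(a = 0.2), T_init = 80,
               s_grid = grid31, v_grid = grid31), "high")
  f_rev <- basin_area_fraction(
    map_basins(loop_params(a = 0.2, variant = "reversed_gaba"), T_init = 80,
               s_grid = grid31, v_grid = grid31), "high")
  expect_gte(f_rev, f_std)
})

test_that("the maximal-T slice is where the zero basin is widest", {
  grid31 <- seq(0, 100, length.out = 31)
  z80 <- basin_area_fraction(
    map_basins(loop_params(a = 0.2), T_init = 80,
               s_grid = grid31, v_grid = grid31), "zero")
  z0 <- basin_area_fraction(
    map_basins(loop_params(a = 0.2), T_init = 0,
               s_grid = grid31, v_grid = grid31), "zero")
  expect_gte(z80, z0)
})

test_that("the switching threshold behaves like an ultrasensitive trigger", {
  expect_identical(attr(switching_threshold(loop_params(a = 1)), "status"),
                   "monostable")
  th <- vapply(c(0.26, 0.20, 0.15), function(a) {
    as.numeric(switching_threshold(loop_params(a = a)))
  }, numeric(1))
  expect_true(all(diff(th) <= 0))          # smaller kick needed as a falls
  # just below the fold the kick is small relative to the high state's V
  eq <- find_equilibria(loop_params(a = 0.26))
  v_high <- eq$V[eq$label == "high"]
  expect_lt(th[1], v_high)
})

test_that("frozen-T slices are exposed but differ from the full 3-D flow", {
  bg3d <- map_basins(loop_params(a = 0.26), T_init = 80,
                     s_grid = grid21, v_grid = grid21)
  bg2d <- map_basins(loop_params(a = 0.26), T_init = 80,
                     s_grid = grid21, v_grid = grid21, freeze_T = TRUE)
  expect_identical(attr(bg2d, "freeze_T"), TRUE)
  expect_equal(nrow(bg2d), nrow(bg3d))
})

test_that("basin tidiers and plots carry the fractions", {
  bg <- map_basins(loop_params(a = 0.26), T_init = 80,
                   s_grid = grid21, v_grid = grid21)
  td <- tidy(bg)
  expect_named(td, c("label", "fraction"))
  expect_equal(sum(td$fraction), 1)
  g <- glance(bg)
  expect_equal(g$n_cells, 441L)
  expect_s3_class(autoplot(bg), "ggplot")
})
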