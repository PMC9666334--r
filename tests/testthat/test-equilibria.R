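test_that("the scalar residual vanishes at the origin and brackets three roots when bistable", {
  set.seed(106)
  for (k in 1:10) {
    pr <- random_loop_params(sample(loop_variants, 1))
    expect_identical(steady_state_residual(0, pr), 0)
  }
  v <- seq(1e-9, 105, length.out = 5000)
  r <- steady_state_residual(v, loop_params(a = 0.2))
  s <- sign(r)
  expect_identical(sum(s[-1] != s[-length(s)]), 2L)  # two positive roots + origin
  r1 <- steady_state_residual(v, loop_params(a = 1))
  expect_true(all(sign(r1) < 0))                     # origin is the only root
})

test_that("full inhibition is monostable at a stable origin with eigenvalues -1/tau", {
  eq <- find_equilibria(loop_params(a = 1))
  expect_equal(nrow(eq), 1L)
  expect_identical(eq$label, "zero")
  expect_identical(eq$stability, "stable")
  expect_equal(eq$eigenvalues[[1]], rep(-2 + 0i, 3))
})

test_that("weak inhibition yields the ordered stable-unstable-stable triple", {
  eq <- find_equilibria(loop_params(a = 0.2))
  expect_equal(nrow(eq), 3L)
  expect_identical(eq$label, c("zero", "mid", "high"))
  expect_identical(eq$stability, c("stable", "unstable", "stable"))
  # componentwise ordering
  for (col in c("S", "T", "V")) expect_true(all(diff(eq[[col]]) > 0))
  # residual of the reconstructed states under the full dynamics
  for (i in 1:3) {
    st <- as.numeric(eq[i, c("S", "T", "V")])
    expect_lt(max(abs(loop_rhs(st, loop_params(a = 0.2)))), 1e-8)
  }
})

test_that("the high equilibrium just below the fold sits at its frozen coordinates", {
  # frozen from an independent scalar-reduction root search (uniroot on a
  # dense bracket of the composed residual)
  eq <- find_equilibria(loop_params(a = 0.26))
  high <- eq[eq$label == "high", ]
  expect_equal(high$V, 29.3188, tolerance = 1e-4)
  expect_equal(high$S, 72.2369, tolerance = 1e-4)
  expect_equal(high$T, 78.6464, tolerance = 1e-4)
})

test_that("find_equilibria matches the brute-force oracle on random parameter sets", {
  set.seed(107)
  for (k in 1:50) {
    pr <- random_loop_params(sample(c("standard", "reversed_gaba"), 1))
    got <- find_equilibria(pr)$V
    want <- oracle_roots(pr, n = 50000)
    expect_equal(length(got), length(want))
    expect_lt(max(abs(got - want)), 1e-4)
  }
})

test_that("equilibrium count is odd and ordered across the efficacy range", {
  for (a in seq(0, 1, length.out = 50)) {
    eq <- find_equilibria(loop_params(a = a))
    expect_true(nrow(eq) %% 2L == 1L)
    expect_identical(eq$label[1], "zero")
    expect_identical(eq$stability[1], "stable")
    if (nrow(eq) >= 3L) {
      for (col in c("S", "T", "V")) expect_true(all(diff(eq[[col]]) > 0))
    }
  }
})

test_that("the reversed-GABA variant keeps two stable equilibria at any efficacy", {
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    g <- glance(find_equilibria(loop_params(a = a, variant = "reversed_gaba")))
    expect_equal(g$n_stable, 2L)
    expect_true(g$bistable)
  }
})

test_that("tidiers expose the per-equilibrium table and the summary row", {
  eq <- find_equilibria(loop_params(a = 0.2))
  td <- tidy(eq)
  expect_named(td, c("label", "S", "T", "V", "stability", "max_re_eigen"))
  g <- glance(eq)
  expect_equal(g$n_equilibria, 3L)
  expect_equal(g$n_stable, 2L)
  expect_true(g$bistable)
})
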