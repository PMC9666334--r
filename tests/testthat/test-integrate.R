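test_that("the origin yields a constant zero trajectory", {
  tr <- simulate_loop(loop_params(a = 0.3), c(0, 0, 0), horizon = 10)
  expect_equal(nrow(tr), 101L)
  expect_true(all(tr$S == 0 & tr$T == 0 & tr$V == 0))
})

test_that("trajectories agree with an independent lsoda integration", {
  pr <- loop_params(a = 0.2)
  tr <- simulate_loop(pr, c(5, 0, 5), horizon = 50, dt_out = 0.5)
  ref <- deSolve::ode(
    y = c(S = 5, T = 0, V = 5),
    times = seq(0, 50, by = 0.5),
    func = function(t, y, parms) list(unname(loop_rhs(pmax(y, 0), pr))),
    parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(as.matrix(tr[, c("S", "T", "V")]) - ref[, 2:4])), 1e-4)
})

test_that("halving the tolerances barely moves the final state", {
  pr <- loop_params(a = 0.2)
  f1 <- simulate_loop(pr, c(5, 0, 5), horizon = 100, dt_out = 100,
                      rtol = 1e-8, atol = 1e-10)
  f2 <- simulate_loop(pr, c(5, 0, 5), horizon = 100, dt_out = 100,
                      rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(as.matrix(f1[2, 2:4]) - as.matrix(f2[2, 2:4]))), 1e-4)
})

test_that("the fixed-step RK4 mode is reproducible and close to the adaptive run", {
  pr <- loop_params(a = 0.2)
  r1 <- simulate_loop(pr, c(5, 0, 5), horizon = 20, method = "rk4")
  r2 <- simulate_loop(pr, c(5, 0, 5), horizon = 20, method = "rk4")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  ad <- simulate_loop(pr, c(5, 0, 5), horizon = 20)
  expect_lt(max(abs(r1$V - ad$V)), 1e-4)
})

test_that("the state box is forward invariant (up to a 1% inflation)", {
  set.seed(105)
  for (k in 1:5) {
    a <- runif(1)
    pr <- loop_params(a = a)
    st <- c(runif(1, 0, 100), runif(1, 0, 80), runif(1, 0, 100))
    tr <- simulate_loop(pr, st, horizon = 100, dt_out = 0.2)
    expect_true(all(tr$S >= -1e-6 & tr$S <= 1.01 * 100))
    expect_true(all(tr$T >= -1e-6 & tr$T <= 1.01 * 80))
    expect_true(all(tr$V >= -1e-6 & tr$V <= 1.01 * 100))
  }
})

test_that("settle classifies deep-basin starts and is idempotent", {
  pr <- loop_params(a = 0.1)
  eq <- find_equilibria(pr)
  expect_identical(settle(pr, c(0, 0, 0), eq), "zero")
  expect_identical(settle(pr, c(100, 0, 100), eq), "high")
  # idempotence: settling from the matched equilibrium returns its own label
  high <- as.numeric(eq[eq$label == "high", c("S", "T", "V")])
  expect_identical(settle(pr, high, eq), "high")
  zero <- as.numeric(eq[eq$label == "zero", c("S", "T", "V")])
  expect_identical(settle(pr, zero, eq), "zero")
})

test_that("simulation from a bistable start converges onto the root-found equilibrium", {
  pr <- loop_params(a = 0.2)
  eq <- find_equilibria(pr)
  high <- as.numeric(eq[eq$label == "high", c("S", "T", "V")])
  # a modest VPL activation beyond the switching threshold (~13 Hz here)
  tr <- simulate_loop(pr, c(5, 0, 20), horizon = 150, dt_out = 150)
  expect_lt(max(abs(as.numeric(tr[2, 2:4]) - high)), 1e-4)
  # while a sub-threshold start relaxes back to baseline
  tr0 <- simulate_loop(pr, c(5, 0, 5), horizon = 150, dt_out = 150)
  expect_lt(max(abs(as.numeric(tr0[2, 2:4]))), 1e-4)
})

test_that("invalid integration arguments are rejected", {
  expect_error(simulate_loop(loop_params(), c(0, 0, 0), horizon = -1),
               "horizon")
  expect_error(simulate_loop(loop_params(), c(0, 0, 0), horizon = 1,
                             dt_out = 0), "dt_out")
  expect_error(simulate_loop(loop_params(), c(-1, 0, 0), horizon = 1),
               "non-negative")
})
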