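test_that("the saddle-node threshold lands on its frozen location", {
  # frozen from an independent bisection over the brute-force root count
  fold <- find_threshold(loop_params())
  expect_identical(fold$status, "fold")
  expect_equal(fold$a_hat, 0.264206, tolerance = 2e-3)
  expect_lt(abs(fold$a_hat - 0.264206), 5e-4)
})

test_that("the threshold is stable under doubling of the scan resolution", {
  a1 <- find_threshold(loop_params(), n_scan = 5000)$a_hat
  a2 <- find_threshold(loop_params(), n_scan = 10000)$a_hat
  expect_lt(abs(a1 - a2), 1e-4)
})

test_that("frozen-parameter variants shift the fold rightward or remove it", {
  std <- find_threshold(loop_params())$a_hat
  fh <- find_threshold(loop_params(variant = "fixed_h"))
  expect_identical(fh$status, "fold")
  expect_gt(fh$a_hat, std)
  fg <- find_threshold(loop_params(variant = "fixed_g"))
  expect_identical(fg$status, "bistable_throughout")   # fold beyond a = 1
})

test_that("degenerate m2 = 0 removes any dependence on the efficacy", {
  fold <- find_threshold(loop_params(m2 = 0))
  expect_identical(fold$status, "bistable_throughout")
  expect_true(is.na(fold$a_hat))
})

test_that("sweeps produce the expected branch structure on both sides of the fold", {
  mono <- bifurcation_sweep(loop_params(), a_grid = seq(0.5, 1, by = 0.05))
  expect_true(all(mono$label == "zero"))
  expect_equal(dplyr::n_distinct(mono$branch), 1L)

  bi <- bifurcation_sweep(loop_params(), a_grid = seq(0, 0.25, by = 0.01))
  counts <- dplyr::count(tibble::as_tibble(bi), a)
  expect_true(all(counts$n == 3L))
  expect_equal(dplyr::n_distinct(bi$branch), 3L)
  # matched branches move continuously
  jumps <- bi |>
    dplyr::arrange(branch, a) |>
    dplyr::group_by(branch) |>
    dplyr::summarise(j = max(abs(diff(V)), 0), .groups = "drop")
  expect_true(all(jumps$j < 5))
})

test_that("the reversed-GABA sweep carries two stable branches over the whole range", {
  sw <- bifurcation_sweep(loop_params(variant = "reversed_gaba"),
                          a_grid = seq(0, 1, by = 0.1))
  st <- dplyr::count(dplyr::filter(tibble::as_tibble(sw),
                                   stability == "stable"), a)
  expect_true(all(st$n == 2L))
})

test_that("the switch shows one-way hysteresis across the fold", {
  pr_lo <- loop_params(a = 0.25)           # just below the fold
  eq_lo <- find_equilibria(pr_lo)
  high <- as.numeric(eq_lo[eq_lo$label == "high", c("S", "T", "V")])
  # raise a above the fold: the high state collapses to baseline
  pr_hi <- loop_params(a = 0.5)
  expect_identical(settle(pr_hi, high), "zero")
  # lower a again: the baseline state stays at baseline (no spontaneous re-excitation)
  expect_identical(settle(pr_lo, c(0, 0, 0), eq_lo), "zero")
})

test_that("sweep tidiers summarise the grid", {
  sw <- bifurcation_sweep(loop_params(), a_grid = seq(0.2, 0.3, by = 0.01))
  g <- glance(sw)
  expect_equal(g$n_a, 11L)
  expect_equal(g$a_multi_max, 0.26)        # last grid point below the fold
})
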