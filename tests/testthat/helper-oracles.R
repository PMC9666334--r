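# Independent oracles built from plain arithmetic, deliberately not reusing
# the package's kinetics or residual code paths.

# right-hand side assembled by direct composition of the Hill expressions
oracle_rhs <- function(state, pr) {
  S <- state[1]; T <- state[2]; V <- state[3]
  f <- function(x, m) m * x^pr$p / (pr$e^pr$p + x^pr$p)
  drive <- switch(pr$variant,
    reversed_gaba = f(S + T, pr$m1),
    {
      u <- pr$a * T
      gv <- if (pr$variant == "fixed_g") pr$m1 else pr$m1 / (1 + (u / pr$e)^pr$p)
      hv <- if (pr$variant == "fixed_h") pr$e0 else pr$e0 + f(u, pr$m2)
      if (S == 0) 0 else gv * S^pr$p / (S^pr$p + hv^pr$p)
    })
  c(f(V, pr$m1) - S, f(V + S, pr$m2) - T, drive - V) / pr$tau
}

oracle_residual <- function(V, pr) {
  f <- function(x, m) m * x^pr$p / (pr$e^pr$p + x^pr$p)
  S <- f(V, pr$m1)
  T <- f(V + S, pr$m2)
  drive <- switch(pr$variant,
    reversed_gaba = f(S + T, pr$m1),
    {
      u <- pr$a * T
      gv <- if (pr$variant == "fixed_g") pr$m1 else pr$m1 / (1 + (u / pr$e)^pr$p)
      hv <- if (pr$variant == "fixed_h") pr$e0 else pr$e0 + f(u, pr$m2)
      gv * S^pr$p / (S^pr$p + hv^pr$p)
    })
  drive - V
}

# brute-force root set from a dense sign-change scan of the independent
# residual, refined with uniroot on that same residual
oracle_roots <- function(pr, n = 50000) {
  vg <- seq(0, 1.05 * pr$m1, length.out = n + 1)[-1]
  r <- oracle_residual(vg, pr)
  s <- sign(r)
  idx <- which(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0)
  roots <- vapply(idx, function(i) {
    uniroot(function(v) oracle_residual(v, pr),
            lower = vg[i], upper = vg[i + 1], tol = 1e-12)$root
  }, numeric(1))
  sort(c(0, vg[s == 0], roots))
}

random_loop_params <- function(variant = "standard") {
  loop_params(
    tau = runif(1, 0.2, 1),
    m1 = runif(1, 60, 140),
    m2 = runif(1, 40, 120),
    e = runif(1, 10, 40),
    e0 = runif(1, 10, 40),
    p = runif(1, 1.5, 4),
    a = runif(1),
    variant = variant
  )
}

random_state <- function(pr, margin = 1) {
  c(runif(1, margin, pr$m1), runif(1, margin, pr$m2), runif(1, margin, pr$m1))
}

fd_jacobian <- function(state, pr) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- 1e-6 * max(1, abs(state[j]))
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (oracle_rhs(up, pr) - oracle_rhs(dn, pr)) / (2 * h)
  }
  J
}
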