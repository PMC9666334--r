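#' Right-hand side of the loop ODE system
#'
#' Evaluates the time derivatives of the three mean firing rates
#' (S: somatosensory cortex, T: thalamic reticular nucleus, V:
#' ventroposterolateral nucleus):
#' \deqn{\tau \dot S + S = f(V), \quad \tau \dot T + T = f_2(V + S),}
#' \deqn{\tau \dot V + V = g(aT)\, S^p / (S^p + h(aT)^p),}
#' where f and f2 are increasing Hill responses with maximal rates m1 and
#' m2, g is the decreasing gain [gain_g()] and h the increasing
#' half-activation shift [shift_h()]. The `reversed_gaba` variant replaces
#' the V equation by \eqn{\tau \dot V + V = f(S + T)}; `fixed_g` and
#' `fixed_h` freeze g at m1 and h at e0 respectively.
#'
#' @param state Numeric vector `(S, T, V)` of firing rates (Hz),
#'   componentwise non-negative.
#' @param params A [loop_params()] object.
#'
#' @return For `loop_rhs()`, a named numeric vector `(S, T, V)` of
#'   derivatives (Hz/s). For `loop_jacobian()`, the 3x3 matrix of partial
#'   derivatives (1/s) of the right-hand side, evaluated analytically.
#' @examples
#' loop_rhs(c(0, 0, 0), loop_params())        # the origin is an equilibrium
#' loop_jacobian(c(0, 0, 0), loop_params())   # diag(-1/tau) for p > 1
#' @export
loop_rhs <- function(state, params) {
  params <- as_loop_params(params)
  state <- check_state(state)
  out <- cpp_rhs(state, param_vector(params))
  setNames(out, c("S", "T", "V"))
}

#' @rdname loop_rhs
#' @export
loop_jacobian <- function(state, params) {
  params <- as_loop_params(params)
  state <- check_state(state)
  S <- state[1]; T <- state[2]; V <- state[3]
  tau <- params$tau; m1 <- params$m1; m2 <- params$m2
  e <- params$e; e0 <- params$e0; p <- params$p; a <- params$a

  dfV  <- hill_f_deriv(V, m1, e, p)
  df2  <- hill_f_deriv(V + S, m2, e, p)

  if (params$variant == "reversed_gaba") {
    dF <- hill_f_deriv(S + T, m1, e, p)
    dFdS <- dF
    dFdT <- dF
  } else {
    u  <- a * T
    gv <- if (params$variant == "fixed_g") m1 else gain_g(u, params)
    hv <- if (params$variant == "fixed_h") e0 else shift_h(u, params)
    dg <- if (params$variant == "fixed_g") 0 else -hill_f_deriv(u, m1, e, p)
    dh <- if (params$variant == "fixed_h") 0 else hill_f_deriv(u, m2, e, p)
    hp <- hv^p
    if (S == 0) {
      dFdS <- if (p > 1) 0 else if (p == 1) gv / hv else Inf
      dFdT <- 0
    } else {
      Sp <- S^p
      dFdS <- gv * p * S^(p - 1) * hp / (Sp + hp)^2
      dFdT <- a * (dg * Sp / (Sp + hp) -
                     gv * Sp * p * hv^(p - 1) * dh / (Sp + hp)^2)
    }
  }

  J <- matrix(c(-1,   0,    dfV,
                df2,  -1,   df2,
                dFdS, dFdT, -1),
              nrow = 3, byrow = TRUE) / tau
  dimnames(J) <- list(c("S", "T", "V"), c("S", "T", "V"))
  J
}
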