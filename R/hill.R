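#' Hill-type interaction functions
#'
#' The three scalar response functions that build the loop dynamics.
#'
#' `hill_f()` is the increasing Hill response `m * x^p / (e^p + x^p)`, used
#' for every excitatory projection; it is strictly increasing in `x`,
#' satisfies `hill_f(0) = 0` (with `0^p` defined as 0 for p > 0) and is
#' bounded above by `m`.
#'
#' `gain_g()` is the decreasing gain modulation `m1 / (1 + (x/e)^p)`
#' exerted by effective TRN inhibition `x = a * T` on the maximal VPL output:
#' `gain_g(0) = m1` and the gain falls to `m1/2` at `x = e`.
#'
#' `shift_h()` is the rightward shift of the VPL half-activation,
#' `e0 + m2 * x^p / (e^p + x^p)`: increasing, with basal value
#' `shift_h(0) = e0`.
#'
#' @param x Input firing rate (Hz); non-negative. For `gain_g()` and
#'   `shift_h()` this is the effective inhibition `a * T`. Vectorised.
#' @param m,e,p Maximal rate (Hz), half-activation rate (Hz) and Hill
#'   exponent for `hill_f()`.
#' @param params A [loop_params()] object supplying `m1`, `m2`, `e`, `e0`
#'   and `p` for `gain_g()` and `shift_h()`.
#'
#' @return A numeric vector of output firing rates (Hz), same length as `x`.
#' @examples
#' hill_f(20, 100, 20, 2.5)          # half-maximal: 50
#' gain_g(c(0, 20), loop_params())   # 100, 50
#' shift_h(20, loop_params())        # e0 + m2/2 = 60
#' @export
hill_f <- function(x, m, e, p) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be finite and non-negative (firing rate).")
  }
  m * x^p / (e^p + x^p)
}

#' @rdname hill_f
#' @export
gain_g <- function(x, params) {
  params <- as_loop_params(params)
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be finite and non-negative (effective inhibition a*T).")
  }
  params$m1 / (1 + (x / params$e)^params$p)
}

#' @rdname hill_f
#' @export
shift_h <- function(x, params) {
  params <- as_loop_params(params)
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be finite and non-negative (effective inhibition a*T).")
  }
  params$e0 + hill_f(x, params$m2, params$e, params$p)
}

# derivative of hill_f w.r.t. x, handling the x = 0 boundary for p != 1
hill_f_deriv <- function(x, m, e, p) {
  if (x == 0) {
    if (p > 1) return(0)
    if (p == 1) return(m / e)
    return(Inf)                  # p < 1: one-sided derivative diverges
  }
  m * p * e^p * x^(p - 1) / (e^p + x^p)^2
}
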