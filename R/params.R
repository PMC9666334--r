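#' Model variants
#'
#' Variant selectors understood throughout the package:
#' `"standard"` is the full loop with inhibitory TRN feedback acting on both
#' the gain and the half-activation of the VPL response; `"reversed_gaba"`
#' turns the TRN projection excitatory (chloride-gradient inversion), so the
#' VPL equation becomes a single increasing Hill response to S + T;
#' `"fixed_g"` freezes the gain at its uninhibited value m1; `"fixed_h"`
#' freezes the half-activation shift at its basal value e0.
#'
#' @format A character vector of the four variant names.
#' @export
loop_variants <- c("standard", "reversed_gaba", "fixed_g", "fixed_h")

variant_code <- function(variant) {
  match(variant, loop_variants) - 1L
}

#' Parameters of the thalamocortical loop model
#'
#' Constructs the validated parameter set shared by every function in the
#' package. Defaults are the nominal values used throughout: a common time
#' constant of 0.5 s, maximal excitatory and inhibitory output rates of 100
#' and 80 Hz, half-activation input rate of 20 Hz, Hill coefficient 2.5, and
#' full GABAergic efficacy (a = 1). The basal half-activation constant `e0`
#' of the shift function defaults to `e`, which makes the VPL equation
#' collapse to the plain excitatory Hill response when a = 0.
#'
#' @param tau Time constant of every population (seconds); > 0.
#' @param m1 Maximal output firing rate of excitatory fibers (Hz); > 0.
#' @param m2 Maximal output firing rate of inhibitory fibers (Hz); > 0.
#' @param e Input firing rate giving half-maximal output (Hz); > 0.
#' @param e0 Basal half-activation constant of the shift function (Hz);
#'   > 0, defaults to `e`.
#' @param p Hill coefficient (dimensionless); > 0.
#' @param a GABAergic efficacy coefficient, in `[0, 1]`.
#' @param variant Model variant, one of [loop_variants].
#'
#' @return An object of class `loop_params`: a named list of the validated
#'   parameters.
#' @examples
#' loop_params()                      # nominal monostable configuration
#' loop_params(a = 0.2)               # bistable regime
#' loop_params(variant = "reversed_gaba")
#' @export
loop_params <- function(tau = 0.5, m1 = 100, m2 = 80, e = 20, e0 = e,
                        p = 2.5, a = 1,
                        variant = c("standard", "reversed_gaba",
                                    "fixed_g", "fixed_h")) {
  variant <- match.arg(variant)
  check_scalar <- function(x, name, lower = 0, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort(sprintf("`%s` must be a single finite number.", name))
    }
    if (strict && x <= lower) {
      abort(sprintf("`%s` must be > %g (got %g).", name, lower, x))
    }
    as.numeric(x)
  }
  tau <- check_scalar(tau, "tau")
  m1  <- check_scalar(m1, "m1")
  m2  <- check_scalar(m2, "m2", strict = FALSE)
  e   <- check_scalar(e, "e")
  e0  <- check_scalar(e0, "e0")
  p   <- check_scalar(p, "p")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0 || a > 1) {
    abort(sprintf("`a` must lie in [0, 1] (got %s).", format(a)))
  }
  if (m2 < 0) abort("`m2` must be >= 0.")
  structure(
    list(tau = tau, m1 = m1, m2 = m2, e = e, e0 = e0, p = p,
         a = as.numeric(a), variant = variant),
    class = "loop_params"
  )
}

#' @export
print.loop_params <- function(x, ...) {
  cat("<loop_params> variant =", x$variant, "\n")
  cat(sprintf("  tau = %g s, m1 = %g Hz, m2 = %g Hz, e = %g Hz, e0 = %g Hz, p = %g, a = %g\n",
              x$tau, x$m1, x$m2, x$e, x$e0, x$p, x$a))
  invisible(x)
}

#' Coerce to loop parameters
#'
#' A `loop_params` object passes through; a named list (e.g. parsed from a
#' config file) is validated through [loop_params()], with omitted entries
#' taking the nominal defaults.
#'
#' @param x A `loop_params` object or a named list of parameter overrides.
#' @return A `loop_params` object.
#' @export
as_loop_params <- function(x) {
  if (inherits(x, "loop_params")) return(x)
  if (!is.list(x)) abort("`x` must be a loop_params object or a named list.")
  allowed <- c("tau", "m1", "m2", "e", "e0", "p", "a", "variant")
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort(sprintf("unknown parameter key(s): %s", paste(extra, collapse = ", ")))
  }
  do.call(loop_params, x)
}

# packed numeric vector consumed by the compiled core
param_vector <- function(params) {
  c(params$tau, params$m1, params$m2, params$e, params$e0, params$p,
    params$a, variant_code(params$variant))
}

# with_a(params, a) -- cheap copy with a replaced, revalidated
with_a <- function(params, a) {
  params$a <- a
  as_loop_params(unclass(params))
}

check_state <- function(state, arg = "state") {
  if (!is.numeric(state) || length(state) != 3L || any(!is.finite(state))) {
    abort(sprintf("`%s` must be a finite numeric vector (S, T, V) of length 3.", arg))
  }
  if (any(state < 0)) {
    abort(sprintf("`%s` must be componentwise non-negative (firing rates).", arg))
  }
  as.numeric(state)
}
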