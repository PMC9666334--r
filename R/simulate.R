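#' Integrate a trajectory of the loop system
#'
#' Integrates the three-population ODE system from a given initial state
#' with an adaptive Dormand--Prince 5(4) stepper (relative tolerance 1e-8,
#' absolute 1e-10 by default), sampling the solution at a fixed output
#' interval. A fixed-step classical RK4 mode is available for
#' bit-reproducible output across platforms. The dynamics are mildly stiff
#' at most (a single shared time constant), so an explicit embedded
#' Runge--Kutta pair is appropriate.
#'
#' @param params A [loop_params()] object.
#' @param initial Initial state `(S, T, V)` in Hz, componentwise
#'   non-negative.
#' @param horizon Integration horizon (seconds); > 0.
#' @param dt_out Output sampling interval (seconds); > 0.
#' @param method `"dp45"` (adaptive, default) or `"rk4"` (fixed step).
#' @param rtol,atol Relative and absolute integration tolerances
#'   (adaptive mode).
#' @param h_fixed Step size for the fixed-step mode (seconds); the output
#'   interval is subdivided into an integer number of steps of at most
#'   this size.
#' @param freeze_T If `TRUE`, holds T at its initial value (diagnostic
#'   frozen-slice mode used for comparing basin sections); the default
#'   integrates the full 3-D flow.
#'
#' @return A tibble of class `loop_trajectory` with columns `time`, `S`,
#'   `T`, `V`; the parameter set, initial state and method are attached as
#'   attributes.
#' @examples
#' simulate_loop(loop_params(a = 0.2), c(5, 0, 5), horizon = 20)
#' @export
simulate_loop <- function(params, initial, horizon, dt_out = 0.1,
                          method = c("dp45", "rk4"),
                          rtol = 1e-8, atol = 1e-10, h_fixed = 0.01,
                          freeze_T = FALSE) {
  params <- as_loop_params(params)
  initial <- check_state(initial, "initial")
  method <- match.arg(method)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    abort("`horizon` must be a single positive number of seconds.")
  }
  if (!is.numeric(dt_out) || length(dt_out) != 1L || dt_out <= 0) {
    abort("`dt_out` must be a single positive number of seconds.")
  }
  m <- cpp_integrate(initial, param_vector(params), horizon, dt_out,
                     rtol, atol, if (method == "dp45") 0L else 1L,
                     h_fixed, freeze_T)
  out <- as_tibble(as.data.frame(m))
  structure(out, params = params, initial = initial, method = method,
            class = c("loop_trajectory", class(out)))
}

#' Classify the attractor reached from an initial state
#'
#' Integrates the system until the trajectory is simultaneously within
#' `tol_attract` (max-norm, Hz) of a stable equilibrium and moving slower
#' than `tol_speed` (max-norm of the right-hand side, Hz/s), or until the
#' horizon runs out. Requiring both proximity and low speed avoids
#' mislabelling slow passages near the unstable saddle. States that fail to
#' resolve within the horizon (e.g. starts on the separatrix) return
#' `"unresolved"`, which is a value rather than an error.
#'
#' @inheritParams simulate_loop
#' @param equilibria Optional `loop_equilibria` object for `params` (as
#'   returned by [find_equilibria()]); computed on the fly when omitted.
#'   Must contain every stable fixed point of the parameter set.
#' @param tol_attract Proximity tolerance (Hz, max-norm).
#' @param tol_speed Speed tolerance (Hz/s, max-norm).
#' @param max_horizon Maximum integration time (seconds).
#'
#' @return A single string: the label of the matched stable equilibrium
#'   (e.g. `"zero"`, `"high"`) or `"unresolved"`.
#' @examples
#' settle(loop_params(a = 0.2), c(100, 0, 100))   # deep in the high basin
#' @export
settle <- function(params, initial, equilibria = NULL,
                   tol_attract = 0.5, tol_speed = 1e-3, max_horizon = 200,
                   rtol = 1e-8, atol = 1e-10, freeze_T = FALSE) {
  params <- as_loop_params(params)
  initial <- check_state(initial, "initial")
  if (is.null(equilibria)) equilibria <- find_equilibria(params)
  stable <- stable_matrix(equilibria)
  if (nrow(stable) == 0L) abort("no stable equilibria to settle to.")
  idx <- cpp_settle(initial, param_vector(params), stable,
                    tol_attract, tol_speed, max_horizon,
                    rtol, atol, dt_check = 0.25, freeze_T = freeze_T)
  if (idx == 0L) "unresolved" else rownames(stable)[idx]
}

#' @export
print.loop_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("# Trajectory of the %s loop at a = %g (%s integrator)\n",
              p$variant, p$a, attr(x, "method")))
  NextMethod()
}

#' Plot a trajectory
#'
#' Draws the three firing rates against time.
#'
#' @param object A `loop_trajectory` from [simulate_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loop_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("S", "T", "V"),
                              names_to = "population", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$rate,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "mean firing rate (Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
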