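#' Map basins of attraction on a 2-D slice of initial conditions
#'
#' Classifies every cell of an (S0, V0) grid of initial conditions by the
#' attractor its trajectory reaches, with the initial TRN rate fixed at
#' `T_init`. The full three-dimensional flow is integrated from each cell
#' (the slices are initial-condition sections of the 3-D flow, not a
#' reduced 2-D system); a frozen-T mode that instead holds T constant is
#' available behind `freeze_T` for comparison. Cells that do not resolve
#' within the horizon are labelled `"unresolved"` and counted, never
#' silently relabelled; with the planar-like separatrix of this system
#' they are expected only within about one cell width of the basin
#' boundary.
#'
#' @param params A [loop_params()] object.
#' @param T_init Initial TRN firing rate shared by all cells (Hz); the
#'   default 80 is the maximal value of T, the slice on which the
#'   low-firing basin is widest.
#' @param s_grid,v_grid Grid values for the initial S and V (Hz); defaults
#'   are 101 points over `[0, 100]` each, so area fractions are comparable
#'   across runs.
#' @param equilibria Optional precomputed [find_equilibria()] result.
#' @param tol_attract,tol_speed,max_horizon Convergence controls passed to
#'   the classifier (see [settle()]).
#' @param rtol,atol Integration tolerances.
#' @param freeze_T If `TRUE`, hold T frozen at `T_init` during
#'   integration (diagnostic mode).
#'
#' @return A tibble of class `loop_basins` with one row per grid cell:
#'   columns `S0`, `V0` (Hz) and `label` (a stable-equilibrium label or
#'   `"unresolved"`). Attributes: `params`, `T_init`, `equilibria`,
#'   `fractions` (named per-label fractions of all cells, summing to 1)
#'   and `freeze_T`.
#' @examples
#' grid <- map_basins(loop_params(a = 0.2), T_init = 80,
#'                    s_grid = seq(0, 100, length.out = 21),
#'                    v_grid = seq(0, 100, length.out = 21))
#' basin_area_fraction(grid, "high")
#' @export
map_basins <- function(params, T_init = 80,
                       s_grid = seq(0, 100, length.out = 101),
                       v_grid = seq(0, 100, length.out = 101),
                       equilibria = NULL,
                       tol_attract = 0.5, tol_speed = 1e-3,
                       max_horizon = 200, rtol = 1e-8, atol = 1e-10,
                       freeze_T = FALSE) {
  params <- as_loop_params(params)
  if (!is.numeric(T_init) || length(T_init) != 1L || T_init < 0) {
    abort("`T_init` must be a single non-negative firing rate (Hz).")
  }
  if (any(s_grid < 0) || any(v_grid < 0)) {
    abort("grid values must be non-negative firing rates (Hz).")
  }
  if (is.null(equilibria)) equilibria <- find_equilibria(params)
  stable <- stable_matrix(equilibria)
  lab_idx <- cpp_map_basins(s_grid, v_grid, T_init, param_vector(params),
                            stable, tol_attract, tol_speed, max_horizon,
                            rtol, atol, dt_check = 0.25,
                            freeze_T = freeze_T)
  labels <- c("unresolved", rownames(stable))[lab_idx + 1L]
  out <- tibble(
    S0 = rep(s_grid, times = length(v_grid)),
    V0 = rep(v_grid, each = length(s_grid)),
    label = as.vector(labels)
  )
  fr <- table(factor(out$label, levels = c(rownames(stable), "unresolved")))
  fractions <- as.numeric(fr) / nrow(out)
  names(fractions) <- names(fr)
  structure(out, params = params, T_init = T_init,
            equilibria = equilibria, fractions = fractions,
            freeze_T = freeze_T,
            class = c("loop_basins", class(out)))
}

#' @export
print.loop_basins <- function(x, ...) {
  p <- attr(x, "params")
  fr <- attr(x, "fractions")
  cat(sprintf("# Basin map of the %s loop at a = %g, T(0) = %g Hz\n",
              p$variant, p$a, attr(x, "T_init")))
  cat("# area fractions:",
      paste(sprintf("%s = %.3f", names(fr), fr), collapse = ", "), "\n")
  NextMethod()
}

#' Area fraction of a basin
#'
#' Fraction of grid cells carrying a given attractor label; an absent
#' label has fraction 0. Fractions over all labels (including
#' `"unresolved"`) partition the grid and sum to 1.
#'
#' @param grid A `loop_basins` tibble from [map_basins()].
#' @param label Attractor label, e.g. `"high"`, `"zero"` or
#'   `"unresolved"`.
#' @return A single number in `[0, 1]`.
#' @export
basin_area_fraction <- function(grid, label) {
  if (!inherits(grid, "loop_basins")) {
    abort("`grid` must be a loop_basins object from map_basins().")
  }
  mean(grid$label == label)
}

#' @export
glance.loop_basins <- function(x, ...) {
  p <- attr(x, "params")
  fr <- attr(x, "fractions")
  out <- tibble(a = p$a, variant = p$variant, T_init = attr(x, "T_init"),
                n_cells = nrow(x))
  for (nm in names(fr)) out[[paste0("frac_", nm)]] <- fr[[nm]]
  out
}

#' @export
tidy.loop_basins <- function(x, ...) {
  fr <- attr(x, "fractions")
  tibble(label = names(fr), fraction = as.numeric(fr))
}

#' Plot a basin map
#'
#' Raster of the (V0, S0) slice coloured by attractor: the high-firing
#' basin in light blue, the low-firing (zero) basin in light red,
#' unresolved cells in grey. Stable equilibria are drawn as filled dots
#' and unstable ones as open dots where they fall on the slice.
#'
#' @param object A `loop_basins` from [map_basins()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loop_basins <- function(object, ...) {
  eq <- attr(object, "equilibria")
  cols <- c(high = "lightblue", zero = "mistyrose", unresolved = "grey70",
            low = "khaki", mid = "thistle")
  present <- unique(object$label)
  gg <- ggplot2::ggplot(as_tibble(object),
                        ggplot2::aes(.data$V0, .data$S0,
                                     fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols[present]) +
    ggplot2::labs(x = "initial V (Hz)", y = "initial S (Hz)", fill = "basin") +
    ggplot2::theme_minimal()
  if (!is.null(eq)) {
    gg <- gg +
      ggplot2::geom_point(
        data = tidy(eq),
        ggplot2::aes(.data$V, .data$S, shape = .data$stability),
        inherit.aes = FALSE, size = 2, colour = "black", fill = "black") +
      ggplot2::scale_shape_manual(values = c(stable = 16, unstable = 1))
  }
  gg
}

#' Minimal perturbation that flips the switch
#'
#' Starting from the baseline (zero) state, finds by bisection the minimal
#' amplitude of a perturbation along a given state-space ray that lands in
#' the basin of the high-firing attractor — the ultrasensitivity threshold
#' of the bistable switch. The default ray is the pure-V direction,
#' modelling a transient spinothalamic activation of VPL.
#'
#' @param params A [loop_params()] object.
#' @param direction Non-negative, non-zero direction vector `(S, T, V)`;
#'   normalised internally to unit max-norm so the amplitude is in Hz.
#' @param tol Bisection width (Hz) at which to stop.
#' @param max_amplitude Upper end of the search ray (Hz along the
#'   normalised direction); defaults to the box edge `1.05 * m1`.
#' @param ... Convergence controls forwarded to [settle()].
#'
#' @return A single number (Hz) with attribute `status = "switch"`, or
#'   `NA` with status `"monostable"` (no second attractor) or
#'   `"no_switch"` (the whole ray stays in the zero basin).
#' @examples
#' switching_threshold(loop_params(a = 0.2))
#' @export
switching_threshold <- function(params, direction = c(0, 0, 1),
                                tol = 0.01, max_amplitude = NULL, ...) {
  params <- as_loop_params(params)
  if (length(direction) != 3L || any(direction < 0) || all(direction == 0)) {
    abort("`direction` must be a non-negative, non-zero length-3 vector.")
  }
  dir <- direction / max(direction)
  eq <- find_equilibria(params)
  stable <- stable_matrix(eq)
  if (nrow(stable) < 2L) {
    return(structure(NA_real_, status = "monostable"))
  }
  if (is.null(max_amplitude)) max_amplitude <- 1.05 * params$m1
  lab <- function(r) settle(params, r * dir, equilibria = eq, ...)
  if (lab(max_amplitude) == "zero") {
    return(structure(NA_real_, status = "no_switch"))
  }
  lo <- 0; hi <- max_amplitude
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (lab(mid) == "zero") lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, status = "switch")
}
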