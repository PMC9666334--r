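count_equilibria <- function(params, n_scan = 5000) {
  length(scan_roots(params, n_scan = n_scan))
}

#' Locate the saddle-node threshold in the GABAergic efficacy
#'
#' Finds the fold value of the efficacy coefficient a at which the high
#' stable equilibrium and the intermediate unstable one collide, by
#' bisecting on the indicator "the system has three (or more) equilibria"
#' over `a_range`. The per-a equilibrium count comes from the scalar
#' steady-state reduction, which makes each evaluation cheap and robust;
#' no continuation is needed.
#'
#' If the indicator is identical at both ends of the interval there is no
#' fold to locate: the system is either bistable throughout (e.g. the
#' reversed-GABA variant, or the degenerate case m2 = 0 in which T never
#' feeds back) or monostable throughout, and the returned status says
#' which.
#'
#' @param params A [loop_params()] object; the `a` field is ignored.
#' @param tol Bisection width on a at which to stop.
#' @param a_range Interval of a to search, within `[0, 1]`.
#' @param n_scan Scan resolution passed to the equilibrium counter.
#'
#' @return An object of class `loop_fold`: a list with elements `a_hat`
#'   (the fold location, `NA` when there is none), `status` (`"fold"`,
#'   `"bistable_throughout"` or `"monostable_throughout"`), `tol`,
#'   `variant`, and the equilibrium counts at the interval ends.
#' @examples
#' find_threshold(loop_params())     # fold near a = 0.264
#' @export
find_threshold <- function(params, tol = 1e-5, a_range = c(0, 1),
                           n_scan = 5000) {
  params <- as_loop_params(params)
  if (length(a_range) != 2L || a_range[1] >= a_range[2] ||
      a_range[1] < 0 || a_range[2] > 1) {
    abort("`a_range` must be an increasing interval inside [0, 1].")
  }
  multi <- function(a) count_equilibria(with_a(params, a), n_scan) >= 3L
  lo <- a_range[1]; hi <- a_range[2]
  m_lo <- multi(lo); m_hi <- multi(hi)
  n_lo <- count_equilibria(with_a(params, lo), n_scan)
  n_hi <- count_equilibria(with_a(params, hi), n_scan)
  res <- list(a_hat = NA_real_, tol = tol, variant = params$variant,
              a_range = a_range, count_low = n_lo, count_high = n_hi)
  if (m_lo == m_hi) {
    res$status <- if (m_lo) "bistable_throughout" else "monostable_throughout"
    class(res) <- "loop_fold"
    return(res)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (multi(mid) == m_lo) lo <- mid else hi <- mid
  }
  res$a_hat <- (lo + hi) / 2
  res$status <- "fold"
  class(res) <- "loop_fold"
  res
}

#' @export
print.loop_fold <- function(x, ...) {
  if (x$status == "fold") {
    cat(sprintf("<loop_fold> %s variant: saddle-node at a_hat = %.5f (tol %g)\n",
                x$variant, x$a_hat, x$tol))
  } else {
    cat(sprintf("<loop_fold> %s variant: no fold in [%g, %g] (%s)\n",
                x$variant, x$a_range[1], x$a_range[2],
                gsub("_", " ", x$status)))
  }
  invisible(x)
}

#' @export
glance.loop_fold <- function(x, ...) {
  tibble(a_hat = x$a_hat, status = x$status, variant = x$variant,
         tol = x$tol)
}

# greedy nearest-neighbour matching of equilibria to open branches
match_branches <- function(prev_states, prev_ids, states, next_id) {
  n <- nrow(states)
  ids <- integer(n)
  used <- logical(length(prev_ids))
  for (i in seq_len(n)) {
    if (length(prev_ids)) {
      d <- vapply(seq_along(prev_ids), function(j) {
        if (used[j]) Inf else max(abs(states[i, ] - prev_states[j, ]))
      }, numeric(1))
      j <- which.min(d)
      if (is.finite(d[j])) {
        ids[i] <- prev_ids[j]
        used[j] <- TRUE
        next
      }
    }
    ids[i] <- next_id
    next_id <- next_id + 1L
  }
  list(ids = ids, next_id = next_id)
}

#' Bifurcation diagram over the GABAergic efficacy
#'
#' Tabulates every equilibrium as a function of a by running
#' [find_equilibria()] at each grid value and stitching branches across
#' adjacent a by nearest-neighbour matching in state space. The default
#' grid covers the interval where all the structure lives
#' (a from 0 to 0.5, step 0.001).
#'
#' @param params A [loop_params()] object; its `a` field is ignored.
#' @param a_grid Sorted grid of a values within `[0, 1]`.
#' @param n_scan Scan resolution per a.
#'
#' @return A tibble of class `loop_bifurcation` with columns `a`, `branch`
#'   (integer id stable across the sweep), `label`, `S`, `T`, `V`,
#'   `stability`, `max_re_eigen`. The parameter set is attached as
#'   attribute `params`.
#' @examples
#' sweep <- bifurcation_sweep(loop_params(), a_grid = seq(0, 0.5, by = 0.01))
#' glance(sweep)
#' @export
bifurcation_sweep <- function(params, a_grid = seq(0, 0.5, by = 0.001),
                              n_scan = 5000) {
  params <- as_loop_params(params)
  if (is.unsorted(a_grid) || any(a_grid < 0) || any(a_grid > 1)) {
    abort("`a_grid` must be sorted and lie within [0, 1].")
  }
  prev_states <- matrix(numeric(0), 0, 3)
  prev_ids <- integer(0)
  next_id <- 1L
  rows <- vector("list", length(a_grid))
  for (k in seq_along(a_grid)) {
    eq <- tidy(find_equilibria(with_a(params, a_grid[k]), n_scan = n_scan))
    states <- as.matrix(eq[, c("S", "T", "V")])
    m <- match_branches(prev_states, prev_ids, states, next_id)
    rows[[k]] <- dplyr::mutate(eq, a = a_grid[k], branch = m$ids,
                               .before = 1)
    prev_states <- states
    prev_ids <- m$ids
    next_id <- m$next_id
  }
  out <- dplyr::bind_rows(rows)
  structure(out, params = params,
            class = c("loop_bifurcation", class(out)))
}

#' @export
print.loop_bifurcation <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("# Bifurcation sweep of the %s loop over a in [%g, %g]\n",
              p$variant, min(x$a), max(x$a)))
  NextMethod()
}

#' Tidiers for bifurcation sweeps
#'
#' `tidy()` returns the branch table; `glance()` summarises the sweep
#' (grid extent, number of branches, range of a with three equilibria).
#'
#' @param x A `loop_bifurcation` object from [bifurcation_sweep()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.loop_bifurcation <- function(x, ...) as_tibble(x)

#' @rdname tidy.loop_bifurcation
#' @export
glance.loop_bifurcation <- function(x, ...) {
  counts <- dplyr::count(as_tibble(x), .data$a)
  multi <- counts$a[counts$n >= 3L]
  tibble(
    n_a = nrow(counts),
    a_min = min(counts$a),
    a_max = max(counts$a),
    n_branches = dplyr::n_distinct(x$branch),
    a_multi_max = if (length(multi)) max(multi) else NA_real_
  )
}

#' Plot a bifurcation diagram
#'
#' Draws the equilibrium branches of S, T and V against a, stable branches
#' in blue and unstable ones in red.
#'
#' @param object A `loop_bifurcation` from [bifurcation_sweep()].
#' @param ... Unused.
#' @return A ggplot object (facetted over the three variables).
#' @export
autoplot.loop_bifurcation <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("S", "T", "V"),
                              names_to = "variable", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(.data$a, .data$rate,
                                     group = .data$branch,
                                     colour = .data$stability)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, nrow = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(stable = "blue", unstable = "red")) +
    ggplot2::labs(x = "GABAergic efficacy a",
                  y = "steady-state firing rate (Hz)", colour = NULL) +
    ggplot2::theme_minimal()
}
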