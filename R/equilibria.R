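#' Scalar steady-state residual in V
#'
#' At a fixed point the S and T equations give closed forms
#' `S* = f(V)` and `T* = f2(V + S*)`; substituting these into the V
#' equation leaves a single scalar equation in V. This function returns its
#' residual `R(V) = RHS_V(S*, T*) - V` (Hz); the zeros of `R` are exactly
#' the equilibria of the full three-dimensional system, with the
#' corresponding state recovered from the closed forms.
#'
#' @param V Candidate VPL firing rate(s) (Hz), non-negative. Vectorised.
#' @param params A [loop_params()] object.
#' @return Numeric vector of residuals (Hz), one per element of `V`.
#' @examples
#' steady_state_residual(0, loop_params())   # the origin is always a root
#' @export
steady_state_residual <- function(V, params) {
  params <- as_loop_params(params)
  if (any(!is.finite(V)) || any(V < 0)) {
    abort("`V` must be finite and non-negative (firing rate).")
  }
  S <- hill_f(V, params$m1, params$e, params$p)
  T <- hill_f(V + S, params$m2, params$e, params$p)
  drive <- switch(params$variant,
    reversed_gaba = hill_f(S + T, params$m1, params$e, params$p),
    {
      u  <- params$a * T
      gv <- if (params$variant == "fixed_g") params$m1 else gain_g(u, params)
      hv <- if (params$variant == "fixed_h") params$e0 else shift_h(u, params)
      gv * S^params$p / (S^params$p + hv^params$p)
    })
  drive - V
}

# locate all non-negative roots of the scalar residual by a sign-change scan
# plus bracketed refinement; refines the grid automatically if the total
# root count (including the structural root at 0) comes out even, which
# signals an unresolved tangency near a fold.
scan_roots <- function(params, n_scan = 5000, v_max = NULL,
                       tol_root = 1e-12, dedupe_tol = 1e-6,
                       max_refine = 4) {
  if (is.null(v_max)) v_max <- 1.05 * params$m1
  n <- n_scan
  for (round in seq_len(max_refine + 1L)) {
    vg <- seq(0, v_max, length.out = n + 1L)[-1L]   # exclude the known root at 0
    r <- steady_state_residual(vg, params)
    s <- sign(r)
    hits <- vg[s == 0]                               # grid point exactly on a root
    idx <- which(s[-1L] != s[-length(s)] & s[-1L] != 0 & s[-length(s)] != 0)
    roots <- vapply(idx, function(i) {
      uniroot(function(v) steady_state_residual(v, params),
              lower = vg[i], upper = vg[i + 1L], tol = tol_root)$root
    }, numeric(1))
    roots <- sort(unique(c(0, hits, roots)))
    if (length(roots) > 1L) {
      keep <- c(TRUE, diff(roots) > dedupe_tol)
      roots <- roots[keep]
    }
    if (length(roots) %% 2L == 1L) return(roots)
    n <- n * 4L                                      # tangency: refine and rescan
  }
  warn(sprintf(
    "even equilibrium count (%d) persists after grid refinement; parameters may sit on a fold",
    length(roots)))
  roots
}

eq_labels <- function(n) {
  if (n == 1L) return("zero")
  interior <- n - 2L
  mids <- if (interior == 1L) "mid"
          else if (interior == 2L) c("low", "mid")
          else paste0("mid", seq_len(interior))
  c("zero", mids, "high")
}

#' Find all equilibria of the loop system
#'
#' Locates every fixed point by scanning the scalar steady-state residual
#' [steady_state_residual()] on a fine V grid over `[0, 1.05 * m1]` (no
#' equilibrium can exceed the Hill ceiling m1), refining each bracketed
#' sign change, reconstructing the full state from the closed forms for S
#' and T, and classifying stability from the eigenvalues of the analytic
#' Jacobian. The origin is an equilibrium of every variant and is always
#' included.
#'
#' @param params A [loop_params()] object.
#' @param n_scan Number of scan intervals for the residual grid.
#' @param v_max Upper end of the scan interval (Hz); default `1.05 * m1`.
#' @param stability_tol Eigenvalue real parts below `-stability_tol`
#'   classify an equilibrium as stable, above `+stability_tol` as unstable;
#'   values within the band raise a marginal-stability warning (relevant
#'   only on a fold).
#'
#' @return A tibble of class `loop_equilibria`, one row per equilibrium,
#'   ordered by V, with columns `label` (`zero`/`low`/`mid`/`high`), `S`,
#'   `T`, `V` (Hz), `stability` (`stable`/`unstable`), `max_re_eigen` (1/s)
#'   and `eigenvalues` (list column of the three complex Jacobian
#'   eigenvalues). The parameter set is attached as attribute `params`.
#' @examples
#' find_equilibria(loop_params(a = 1))     # monostable: origin only
#' find_equilibria(loop_params(a = 0.2))   # bistable: zero, mid, high
#' @export
find_equilibria <- function(params, n_scan = 5000, v_max = NULL,
                            stability_tol = 1e-9) {
  params <- as_loop_params(params)
  V <- scan_roots(params, n_scan = n_scan, v_max = v_max)
  S <- hill_f(V, params$m1, params$e, params$p)
  T <- hill_f(V + S, params$m2, params$e, params$p)

  eig <- lapply(seq_along(V), function(i) {
    ev <- eigen(loop_jacobian(c(S[i], T[i], V[i]), params),
                only.values = TRUE)$values
    as.complex(ev)       # eigen() drops to double when all roots are real
  })
  max_re <- vapply(eig, function(ev) max(Re(ev)), numeric(1))
  if (any(abs(max_re) <= stability_tol)) {
    warn("marginal equilibrium: leading eigenvalue real part within tolerance of zero")
  }
  out <- tibble(
    label = eq_labels(length(V)),
    S = S, T = T, V = V,
    stability = ifelse(max_re < -stability_tol, "stable", "unstable"),
    max_re_eigen = max_re,
    eigenvalues = eig
  )
  structure(out, params = params,
            class = c("loop_equilibria", class(out)))
}

#' @export
print.loop_equilibria <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("# Equilibria of the %s loop at a = %g\n", p$variant, p$a))
  NextMethod()
}

#' Tidiers for equilibrium sets
#'
#' `tidy()` returns the plain per-equilibrium table (dropping the
#' eigenvalue list column); `glance()` returns a one-row summary with the
#' equilibrium and stable counts and a `bistable` flag.
#'
#' @param x A `loop_equilibria` object from [find_equilibria()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.loop_equilibria <- function(x, ...) {
  as_tibble(x)[c("label", "S", "T", "V", "stability", "max_re_eigen")]
}

#' @rdname tidy.loop_equilibria
#' @export
glance.loop_equilibria <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_equilibria = nrow(x),
    n_stable = sum(x$stability == "stable"),
    bistable = sum(x$stability == "stable") >= 2L,
    a = p$a,
    variant = p$variant
  )
}

# stable equilibria as the (k x 3) matrix expected by the compiled classifier
stable_matrix <- function(equilibria) {
  st <- equilibria[equilibria$stability == "stable", , drop = FALSE]
  m <- as.matrix(st[, c("S", "T", "V")])
  rownames(m) <- st$label
  m
}
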