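signif_cols <- function(df, digits = 10) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  ~ signif(.x, digits)))
}

#' Reproduce the bifurcation-and-basins summary of the loop model
#'
#' One driver tying the analysis together: locates the saddle-node
#' threshold, sweeps the bifurcation diagram of S, T and V over a, and
#' maps basins of attraction on the V/S slice at `T_init` for a monostable
#' exemplar and two bistable values of a just below and well below the
#' fold. All tables are written as plain CSV (numbers at 10 significant
#' digits) plus JSON summaries.
#'
#' Files written to `outdir`: `bifurcation_branches.csv`, `fold.json`,
#' one `basins_a_<value>.csv` per requested a, `basin_fractions.json`,
#' and `equilibria.csv` (the equilibria at each basin a).
#'
#' @param outdir Output directory, created if missing.
#' @param params Base [loop_params()] object (the `a` field is overridden
#'   per stage).
#' @param a_grid Grid of a for the bifurcation sweep.
#' @param a_basins Values of a at which to map basins.
#' @param T_init Initial TRN rate for the basin slices (Hz).
#' @param resolution Basin grid resolution per axis.
#'
#' @return Invisibly, a list with the fold object, the sweep, the basin
#'   maps and the written file paths.
#' @export
run_loop_report <- function(outdir, params = loop_params(),
                            a_grid = seq(0, 0.5, by = 0.001),
                            a_basins = c(1, 0.26, 0.15), T_init = 80,
                            resolution = 101) {
  params <- as_loop_params(params)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  fold <- find_threshold(params)
  p_fold <- file.path(outdir, "fold.json")
  jsonlite::write_json(list(a_hat = fold$a_hat, status = fold$status,
                            variant = fold$variant),
                       p_fold, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p_fold)

  sweep <- bifurcation_sweep(params, a_grid = a_grid)
  p_sweep <- file.path(outdir, "bifurcation_branches.csv")
  readr::write_csv(signif_cols(tidy(sweep)), p_sweep)
  paths <- c(paths, p_sweep)

  grid <- seq(0, 100, length.out = resolution)
  basins <- list()
  eq_rows <- list()
  fractions <- list()
  for (a in a_basins) {
    pa <- with_a(params, a)
    eq <- find_equilibria(pa)
    bg <- map_basins(pa, T_init = T_init, s_grid = grid, v_grid = grid,
                     equilibria = eq)
    tag <- gsub("\\.", "p", format(a))
    p_b <- file.path(outdir, paste0("basins_a_", tag, ".csv"))
    readr::write_csv(signif_cols(as_tibble(bg)), p_b)
    paths <- c(paths, p_b)
    basins[[as.character(a)]] <- bg
    eq_rows[[as.character(a)]] <- dplyr::mutate(tidy(eq), a = a, .before = 1)
    fractions[[as.character(a)]] <- as.list(attr(bg, "fractions"))
  }
  p_fr <- file.path(outdir, "basin_fractions.json")
  jsonlite::write_json(fractions, p_fr, auto_unbox = TRUE, digits = NA)
  p_eq <- file.path(outdir, "equilibria.csv")
  readr::write_csv(signif_cols(dplyr::bind_rows(eq_rows)), p_eq)
  paths <- c(paths, p_fr, p_eq)

  invisible(list(fold = fold, sweep = sweep, basins = basins,
                 paths = paths))
}
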