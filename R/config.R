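config_blocks <- c("simulate", "equilibria", "bifurcation", "basins", "report")
config_scalars <- c("seed", "out_dir", "log_level")
param_keys <- c("tau", "m1", "m2", "e", "e0", "p", "a", "variant")

#' Read and write run configurations
#'
#' A run configuration is a JSON or YAML file whose top level holds model
#' parameter keys (named exactly `tau`, `m1`, `m2`, `e`, `e0`, `p`, `a`,
#' `variant`; omitted keys take the nominal defaults) plus optional
#' command blocks (`simulate`, `equilibria`, `bifurcation`, `basins`,
#' `report`) and the scalars `seed`, `out_dir` and `log_level`. Unknown
#' keys are rejected with a message naming the offender, and parameter
#' values are validated eagerly through [loop_params()] so downstream
#' numerics never see an invalid set. Configurations round-trip losslessly
#' through [write_loop_config()].
#'
#' @param path File path; the format is chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return For `read_loop_config()`, a list of class `loop_config` with
#'   elements `params` (a [loop_params()] object) and any command blocks
#'   and scalars present in the file. For `write_loop_config()`, the path,
#'   invisibly.
#' @examples
#' path <- tempfile(fileext = ".json")
#' writeLines('{"a": 0.2, "variant": "standard"}', path)
#' read_loop_config(path)
#' @export
read_loop_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    abort(sprintf("unsupported config extension '.%s' (use .json, .yml or .yaml)", ext))
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config file must contain a mapping at the top level.")
  allowed <- c(param_keys, config_blocks, config_scalars)
  extra <- setdiff(names(raw), allowed)
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  params <- as_loop_params(raw[intersect(names(raw), param_keys)])
  out <- c(list(params = params),
           raw[intersect(names(raw), c(config_blocks, config_scalars))])
  structure(out, class = "loop_config")
}

#' @rdname read_loop_config
#' @param config A `loop_config` object (or a [loop_params()] object,
#'   which is wrapped).
#' @export
write_loop_config <- function(config, path) {
  if (inherits(config, "loop_params")) config <- structure(list(params = config),
                                                           class = "loop_config")
  if (!inherits(config, "loop_config")) {
    abort("`config` must be a loop_config or loop_params object.")
  }
  flat <- c(unclass(config$params),
            unclass(config)[setdiff(names(config), "params")])
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yml = ,
    yaml = yaml::write_yaml(flat, path),
    abort(sprintf("unsupported config extension '.%s' (use .json, .yml or .yaml)", ext))
  )
  invisible(path)
}

#' @export
print.loop_config <- function(x, ...) {
  cat("<loop_config>\n")
  print(x$params)
  blocks <- setdiff(names(x), "params")
  if (length(blocks)) cat("  blocks:", paste(blocks, collapse = ", "), "\n")
  invisible(x)
}
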