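#' Read a benchmark run configuration
#'
#' A YAML file describing the simulation profile and the mappers to
#' benchmark. Each mapper entry gives the adapter command templates plus
#' either explicit labelled `parameter_sets` (each with `label` and `args`),
#' a `parameter_grid` of value ranges expanded to every cartesian
#' combination via [expand_grid()], or both (explicit sets first, then the
#' grid, in file order).
#'
#' @param path YAML file path.
#' @return list with `simulation` (a [simulation_profile()]) and `mappers`
#'   (list of entries with `adapter` and `parameter_sets`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  sim_args <- cfg$simulation %||% list()
  profile <- do.call(simulation_profile, sim_args)
  mappers <- lapply(cfg$mappers %||% list(), function(mc) {
    if (is.null(mc$name) || is.null(mc$map_command)) {
      stop_config("each mapper needs a name and a map_command")
    }
    adapter <- mapper_adapter(mc$name, mc$map_command, mc$index_command)
    sets <- list()
    for (ps in mc$parameter_sets %||% list()) {
      if (is.null(ps$label)) stop_config("parameter_sets entries need a label")
      sets <- c(sets, list(structure(
        list(label = ps$label, tokens = list(), args = ps$args %||% ""),
        class = "ParameterSet"
      )))
    }
    if (!is.null(mc$parameter_grid)) {
      sets <- c(sets, expand_grid(mc$parameter_grid))
    }
    if (length(sets) == 0L) sets <- list(parameter_set("default"))
    labels <- vapply(sets, `[[`, character(1L), "label")
    if (anyDuplicated(labels)) {
      stop_config(sprintf("duplicate parameter labels for mapper %s",
                          mc$name))
    }
    list(adapter = adapter, parameter_sets = sets)
  })
  list(simulation = profile, mappers = mappers)
}
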