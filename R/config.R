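#' Read a run configuration file
#'
#' Reads a YAML run configuration into the package's configuration
#' objects.  Recognised top-level keys: `world` (arguments of
#' [world_config()]), `survey` (arguments of [survey_config()], including
#' `protocol`), `fish_type` (a packaged type name or a path to a fish-type
#' CSV) and `seed`.
#'
#' @param path path to a YAML file.
#' @return a list with elements `world`, `survey`, `type` and `seed`,
#'   ready for [run_survey()].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading run configurations requires the 'yaml' package")
  cfg <- yaml::read_yaml(path)
  world <- do.call(world_config, as.list(cfg$world))
  survey <- do.call(survey_config, as.list(cfg$survey))
  type <- if (!is.null(cfg$fish_type) && file.exists(cfg$fish_type))
    read_fish_type(cfg$fish_type)
  else
    builtin_fish_types(cfg$fish_type)
  list(world = world, survey = survey, type = type,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}
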