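#' Read a pipeline configuration from YAML
#'
#' The YAML file may contain `design`, `population` (with `mean` and `sd`
#' sub-maps of observer fields), and top-level fitting options (`n_boot`,
#' `n_starts`, `fit_subject_category`, `out_dir`).  Omitted entries fall
#' back to the package defaults, which reproduce the study regime.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the seeds in the file (applied to
#'   both design and population).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  design <- do.call(design_spec, cfg$design %||% list())
  pop_args <- cfg$population %||% list()
  if (!is.null(pop_args$mean)) {
    pop_args$mean <- do.call(observer_params, pop_args$mean)
  }
  population <- do.call(population_spec, pop_args)
  if (!is.null(seed)) {
    design$seed <- as.integer(seed)
    population$seed <- as.integer(seed)
  }
  pipeline_config(
    design = design,
    population = population,
    n_boot = cfg$n_boot %||% 0,
    n_starts = cfg$n_starts %||% 8,
    fit_subject_category = cfg$fit_subject_category %||% TRUE,
    out_dir = cfg$out_dir
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
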