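#' Write a pipeline configuration to JSON
#'
#' The configuration round-trips losslessly: [read_pipeline_config()] on
#' the written file reconstructs an identical object (hash-equal under
#' [run_pipeline()]'s config hash).
#'
#' @param config A [pipeline_config()].
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  json <- jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' @param path A file written by [write_pipeline_config()].
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  d <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_named <- function(x) stats::setNames(as.numeric(x), names(x))
  pipeline_config(
    world = world_config(
      n_ecoregions = d$world$n_ecoregions,
      ports_per_ecoregion = d$world$ports_per_ecoregion,
      n_islands = d$world$n_islands,
      bbox = as_named(unlist(d$world$bbox)),
      purpose_weights = as_named(unlist(d$world$purpose_weights)),
      seed = d$world$seed),
    fleet = fleet_config(
      n_vessels = d$fleet$n_vessels,
      type_mix = as_named(unlist(d$fleet$type_mix)),
      length_params = tibble::as_tibble(d$fleet$length_params)),
    traffic = traffic_config(
      years = d$traffic$years,
      base_intensity = d$traffic$base_intensity,
      growth_rate = d$traffic$growth_rate,
      route_concentration = d$traffic$route_concentration,
      bulker_mining_boost = d$traffic$bulker_mining_boost),
    truth = ground_truth(
      mixture = d$truth$mixture,
      linear = purrr::map(d$truth$linear, function(g) {
        g$purpose_offsets <- as_named(unlist(g$purpose_offsets))
        g
      }),
      exchange_position = as_named(unlist(d$truth$exchange_position)),
      provenance_mismatch_rate = d$truth$provenance_mismatch_rate,
      mismatch_within_ecoregion = d$truth$mismatch_within_ecoregion,
      corruption_rate = d$truth$corruption_rate),
    coeffs = do.call(design_coefficients, as.list(d$coeffs)),
    rules = do.call(curation_rules, as.list(d$rules)),
    candidate_sets = purrr::map(d$candidate_sets, as.character),
    K_range = d$K_range,
    n_restarts = d$n_restarts, tol = d$tol, max_iter = d$max_iter,
    cv_repeats = d$cv_repeats, train_fraction = d$train_fraction,
    speed_knots = d$speed_knots,
    decay = do.call(decay_params, as.list(d$decay)),
    lambda_grid = d$lambda_grid,
    seed = d$seed)
}
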