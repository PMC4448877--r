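#' Serialize a fitted discharge model to JSON
#'
#' Writes a version-stamped JSON document holding the model type and all
#' parameters needed to reproduce predictions, so fitted models can be
#' stored alongside pipeline outputs and reloaded without refitting.
#'
#' @param model A `mixture_discharge` or `linear_discharge` fit.
#' @param path File path to write; with `path = NULL` the JSON string is
#'   returned instead.
#' @return `path` invisibly (or the JSON string).
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- if (inherits(model, "mixture_discharge")) {
    list(format_version = 1L, type = "mixture",
         K = model$K, weights = model$weights, beta1 = model$beta1,
         beta2 = model$beta2, sigma = model$sigma, loglik = model$loglik,
         n = model$n, criteria = as.list(model$criteria))
  } else if (inherits(model, "linear_discharge")) {
    list(format_version = 1L, type = "linear",
         predictors = model$predictors, intercept = model$intercept,
         capacity_slope = model$capacity_slope,
         factor_terms = purrr::map(model$factor_terms,
                                   ~ as.list(tibble::as_tibble(.x))),
         sigma = model$sigma, loglik = model$loglik, n = model$n,
         k = model$k, bic = model$bic, fitted_mean = model$fitted_mean)
  } else {
    stop("not a discharge model", call. = FALSE)
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Load a fitted discharge model from JSON
#'
#' @param path Path to a file written by [model_to_json()].
#' @return The restored model object.
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$format_version) || doc$format_version != 1L) {
    stop("unrecognised model document version", call. = FALSE)
  }
  if (doc$type == "mixture") {
    new_mixture(doc$K, doc$weights, doc$beta1, doc$beta2, doc$sigma,
                doc$loglik, doc$n, trace = doc$loglik, n_iter = NA_integer_)
  } else if (doc$type == "linear") {
    structure(list(
      predictors = doc$predictors, intercept = doc$intercept,
      capacity_slope = doc$capacity_slope,
      factor_terms = purrr::map(doc$factor_terms, tibble::as_tibble),
      sigma = doc$sigma, loglik = doc$loglik, n = doc$n, k = doc$k,
      bic = doc$bic, fitted_mean = doc$fitted_mean),
      class = "linear_discharge")
  } else {
    stop("unknown model type: ", doc$type, call. = FALSE)
  }
}

#' Write shoreline polygons as GeoJSON
#'
#' @param shoreline List of polygon matrices (lon, lat).
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_shoreline_geojson <- function(shoreline, path) {
  feats <- purrr::map(shoreline, function(p) {
    p <- as.matrix(p)
    ring <- rbind(p, p[1, , drop = FALSE])  # close the ring
    list(type = "Feature", properties = list(),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) unname(ring[i, ]))))))
  })
  doc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read shoreline polygons from GeoJSON
#'
#' Accepts a FeatureCollection of simple Polygon features (outer rings
#' only); rings are un-closed back to vertex matrices. Polygons crossing
#' the antimeridian must be pre-split.
#'
#' @param path GeoJSON file.
#' @return List of polygon matrices with lon, lat columns.
#' @export
read_shoreline_geojson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  purrr::map(doc$features, function(f) {
    ring <- do.call(rbind, purrr::map(f$geometry$coordinates[[1]],
                                      ~ unlist(.x)[1:2]))
    colnames(ring) <- c("lon", "lat")
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    ring
  })
}
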