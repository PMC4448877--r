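#' Hindcast ballast discharge over the voyage history
#'
#' Applies the fitted per-type discharge models to every voyage in the
#' shipping table: vessel length gives calculated DWT and ballast
#' capacity, and the type's model gives the expected discharge and its
#' predictive variance. Voyages whose vessel fails the geometry rules
#' (length outside (0, 345]) are excluded and counted. Vessels outside
#' the model's covariate range are extrapolated linearly (flagged with a
#' message when `verbose`).
#'
#' @param voyages Voyage table (`voyage_id`, `vessel_id`, `year`,
#'   `src_port`, `dst_port`).
#' @param vessels Vessel table (`vessel_id`, `type`, `length_m`).
#' @param ports Port table (`port_id`, `ecoregion_id`, `purpose`).
#' @param models_by_type Named list of fitted models, one per vessel type
#'   present in the data (e.g. `bulker` a `mixture_discharge`, the rest
#'   `linear_discharge`).
#' @param coeffs [design_coefficients()].
#' @param rules [curation_rules()] used as the geometry validity check.
#' @return Tibble of hindcast records: voyage identifiers, vessel type,
#'   year, route, ecoregions, `capacity_m3`, `expected_discharge_m3`,
#'   `variance_m6`; the number of excluded voyages is in attribute
#'   `n_excluded`.
#' @export
hindcast_voyages <- function(voyages, vessels, ports, models_by_type,
                             coeffs = design_coefficients(),
                             rules = curation_rules()) {
  v <- dplyr::left_join(tibble::as_tibble(voyages),
                        dplyr::select(tibble::as_tibble(vessels),
                                      "vessel_id", "type", "length_m"),
                        by = "vessel_id")
  missing_models <- setdiff(unique(v$type), names(models_by_type))
  if (length(missing_models)) {
    stop("no discharge model for vessel type(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }
  ok <- !is.na(v$length_m) & v$length_m > 0 &
    v$length_m <= rules$max_length_m
  n_excluded <- sum(!ok)
  v <- v[ok, , drop = FALSE]
  ports <- tibble::as_tibble(ports)
  v$src_ecoregion <- ports$ecoregion_id[match(v$src_port, ports$port_id)]
  v$dst_ecoregion <- ports$ecoregion_id[match(v$dst_port, ports$port_id)]
  v$purpose <- ports$purpose[match(v$dst_port, ports$port_id)]
  v$capacity_m3 <- calc_ballast_capacity(calc_dwt(v$length_m, coeffs),
                                         coeffs)
  v$expected_discharge_m3 <- NA_real_
  v$variance_m6 <- NA_real_
  for (tp in unique(v$type)) {
    i <- which(v$type == tp)
    m <- models_by_type[[tp]]
    args <- list(m, capacity = v$capacity_m3[i], mode = "expected",
                 coeffs = coeffs,
                 max_discharge_fraction_of_dwt =
                   rules$max_discharge_fraction_of_dwt)
    if (inherits(m, "linear_discharge")) {
      for (f in names(m$factor_terms)) args[[f]] <- v[[f]][i]
    }
    pred <- do.call(predict_discharge, args)
    v$expected_discharge_m3[i] <- pred$expected_m3
    v$variance_m6[i] <- pred$variance_m6
  }
  out <- dplyr::select(v, "voyage_id", "vessel_id", vessel_type = "type",
                       "year", "src_port", "dst_port", "src_ecoregion",
                       "dst_ecoregion", "purpose", "capacity_m3",
                       "expected_discharge_m3", "variance_m6")
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Aggregate hindcast discharge
#'
#' Grouped totals of expected discharge and predictive variance (voyages
#' treated as independent, so variances add) with voyage counts. Sums over
#' any complete partition equal the grand total.
#'
#' @param records A [hindcast_voyages()] table.
#' @param by One of `"year"`, `"port"`, `"ecoregion"`, `"route"` (port
#'   and ecoregion group by the arrival side; `"source_port"` /
#'   `"source_ecoregion"` group by the origin side).
#' @return Tibble ordered by grouping key with `total_discharge_m3`,
#'   `total_variance_m6`, `n_voyages`.
#' @export
aggregate_discharge <- function(records, by = c("year", "port", "ecoregion",
                                                "route", "source_port",
                                                "source_ecoregion")) {
  by <- match.arg(by)
  r <- tibble::as_tibble(records)
  if (nrow(r) == 0) stop("no hindcast records", call. = FALSE)
  keys <- switch(by,
                 year = "year",
                 port = "dst_port",
                 ecoregion = "dst_ecoregion",
                 route = c("src_port", "dst_port"),
                 source_port = "src_port",
                 source_ecoregion = "src_ecoregion")
  r |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(total_discharge_m3 = sum(.data$expected_discharge_m3),
                     total_variance_m6 = sum(.data$variance_m6),
                     n_voyages = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Provenance consistency of ballast uptake and discharge
#'
#' The volume-weighted proportion of ballast water whose recorded uptake
#' port matches the voyage's source port (`side = "source"`), or whose
#' discharge port matches the arrival port (`side = "arrival"`), at port,
#' ecoregion, or grouped-ecoregion resolution. Grouping merges named sets
#' of ecoregions (e.g. the waters around the South China Sea, or around
#' Japan and Korea) into super-groups before comparing, so nearby
#' previous ports of call count as consistent. Coarsening can only merge
#' mismatches into matches, so the proportion is non-decreasing from port
#' to ecoregion to grouped level.
#'
#' @param events Ballast event table with `uptake_port`, `discharge_port`,
#'   `src_port`, `dst_port` and `volume_m3`.
#' @param ports Port table mapping `port_id` to `ecoregion_id`.
#' @param level `"port"`, `"ecoregion"` or `"grouped"`.
#' @param side `"source"` (uptake vs voyage source) or `"arrival"`
#'   (discharge vs arrival port).
#' @param groups For `level = "grouped"`: named list of character vectors
#'   of ecoregion ids to merge; defaults to [ecoregion_supergroups()]
#'   (real-world ecoregion names).
#' @return The consistent proportion (scalar in \[0, 1\]); events whose
#'   ports are absent from `ports` at ecoregion level are excluded and
#'   counted in attribute `n_excluded`.
#' @export
provenance_consistency <- function(events, ports,
                                   level = c("port", "ecoregion", "grouped"),
                                   side = c("source", "arrival"),
                                   groups = NULL) {
  level <- match.arg(level)
  side <- match.arg(side)
  ev <- tibble::as_tibble(events)
  ports <- tibble::as_tibble(ports)
  obs <- if (side == "source") ev$uptake_port else ev$discharge_port
  ref <- if (side == "source") ev$src_port else ev$dst_port
  n_excluded <- 0L
  if (level == "port") {
    match_ok <- obs == ref
  } else {
    eco_obs <- ports$ecoregion_id[match(obs, ports$port_id)]
    eco_ref <- ports$ecoregion_id[match(ref, ports$port_id)]
    known <- !is.na(eco_obs) & !is.na(eco_ref)
    n_excluded <- sum(!known)
    if (level == "grouped") {
      if (is.null(groups)) groups <- ecoregion_supergroups()
      remap <- function(e) {
        for (g in names(groups)) e[e %in% groups[[g]]] <- g
        e
      }
      eco_obs <- remap(eco_obs)
      eco_ref <- remap(eco_ref)
    }
    match_ok <- known & eco_obs == eco_ref
    obs_vol <- ev$volume_m3[known]
    out <- sum(ev$volume_m3[known & match_ok]) / sum(obs_vol)
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }
  out <- sum(ev$volume_m3[match_ok]) / sum(ev$volume_m3)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Named ecoregion super-groups
#'
#' The two super-groups used when assessing grouped source-provenance
#' consistency: the waters around the South China Sea, and the waters
#' surrounding Japan and Korea. Useful with real Spalding-scheme
#' ecoregion names; synthetic worlds supply their own grouping.
#'
#' @return Named list of character vectors of ecoregion names.
#' @export
ecoregion_supergroups <- function() {
  list(
    south_china_sea = c("Gulf of Tonkin", "South China Sea Oceanic Islands",
                        "Gulf of Thailand", "Southern Vietnam",
                        "Sunda Shelf/Java Sea", "Malacca Strait"),
    japan_korea = c("Northeastern Honshu", "Sea of Japan", "Yellow Sea",
                    "Central Kuroshio Current", "East China Sea"))
}
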