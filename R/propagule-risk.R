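#' Propagule survival parameters
#'
#' Parameters of the exponential-decay survival model for organism density
#' in ballast water, with an optional mid-ocean ballast-water exchange
#' (BWE) event. A voyage of duration T with BWE a proportion `p_exchange`
#' of the way through, pre-exchange decay rate `mu1`, post-exchange rate
#' `mu2` and survival fraction `r` gives final density
#' \eqn{D(T) = D(0) r e^{-\mu_1 p T} e^{-\mu_2 (1-p) T}}, equivalently
#' \eqn{D(0) r e^{-\lambda T}} with the composite rate
#' \eqn{\lambda = \mu_1 p + \mu_2 (1-p)}.
#'
#' Defaults: initial density D0 = 2113.489 organisms per m3 and decay rate
#' lambda = 0.161 per day (coastal zooplankton survey values); `mu1` and
#' `mu2` both default to `lam`, `p_exchange` to 0.5 (exchange near
#' mid-voyage) and `r` to 1, so the default model reduces to plain
#' exponential decay. D0 and r are pure scale factors: they never change
#' relative rankings.
#'
#' @param D0 Initial organism density (organisms/m3).
#' @param lam Decay rate (per day).
#' @param mu1,mu2 Pre-/post-exchange decay rates (per day).
#' @param p_exchange Proportion of the voyage completed at BWE, in \[0, 1\].
#' @param r Proportion of propagules remaining after BWE, in \[0, 1\].
#' @return An object of class `decay_params`.
#' @export
decay_params <- function(D0 = 2113.489, lam = 0.161, mu1 = lam, mu2 = lam,
                         p_exchange = 0.5, r = 1) {
  if (D0 < 0 || lam < 0 || mu1 < 0 || mu2 < 0) {
    stop("density and decay rates must be non-negative", call. = FALSE)
  }
  if (p_exchange < 0 || p_exchange > 1) {
    stop("p_exchange must be in [0, 1]", call. = FALSE)
  }
  if (r < 0 || r > 1) stop("r must be in [0, 1]", call. = FALSE)
  structure(list(D0 = D0, lam = lam, mu1 = mu1, mu2 = mu2,
                 p_exchange = p_exchange, r = r),
            class = "decay_params")
}

#' Organism density after t days (no exchange)
#'
#' \eqn{D(t) = D(0) e^{-\lambda t}}.
#'
#' @param t_days Voyage duration in days, non-negative (vectorised).
#' @param params A [decay_params()] object.
#' @return Organisms per m3.
#' @examples
#' density_at(0)    # 2113.489
#' density_at(10)   # ~422.5
#' @export
density_at <- function(t_days, params = decay_params()) {
  stopifnot(inherits(params, "decay_params"))
  if (any(t_days < 0, na.rm = TRUE)) {
    stop("duration must be non-negative", call. = FALSE)
  }
  params$D0 * exp(-params$lam * t_days)
}

#' Composite decay rate under ballast-water exchange
#'
#' \eqn{\lambda = \mu_1 p + \mu_2 (1 - p)}: the duration-weighted mean of
#' the pre- and post-exchange decay rates.
#'
#' @param mu1,mu2 Pre-/post-exchange decay rates (per day).
#' @param p_exchange Proportion of the voyage completed at BWE, in \[0, 1\].
#' @return Composite decay rate (per day).
#' @export
composite_lambda <- function(mu1, mu2, p_exchange) {
  if (any(p_exchange < 0 | p_exchange > 1)) {
    stop("p_exchange must be in [0, 1]", call. = FALSE)
  }
  mu1 * p_exchange + mu2 * (1 - p_exchange)
}

#' Organism density after a voyage with ballast-water exchange
#'
#' \eqn{D(T) = D(0) r e^{-\mu_1 p T} e^{-\mu_2 (1-p) T}}. With r = 1 and
#' mu1 = mu2 = lambda this reduces exactly to [density_at()].
#'
#' @param T_days Total voyage duration in days, non-negative (vectorised).
#' @param params A [decay_params()] object.
#' @return Organisms per m3 at discharge.
#' @export
bwe_density <- function(T_days, params = decay_params()) {
  stopifnot(inherits(params, "decay_params"))
  if (any(T_days < 0, na.rm = TRUE)) {
    stop("duration must be non-negative", call. = FALSE)
  }
  p <- params$p_exchange
  params$D0 * params$r *
    exp(-params$mu1 * p * T_days) * exp(-params$mu2 * (1 - p) * T_days)
}

#' Propagule pressure per route and ecoregion
#'
#' Converts hindcast per-voyage discharge into propagule pressure: each
#' voyage contributes expected discharge volume times the surviving
#' organism density at its duration, \eqn{V \cdot D(T)} with D from
#' [bwe_density()]. Contributions are summed per route (source port,
#' destination port) and per source and arrival ecoregion. Total pressure
#' is linear in the volumes; D0 and r scale all totals equally.
#'
#' @param hindcast_records Tibble with columns `src_port`, `dst_port`,
#'   `src_ecoregion`, `dst_ecoregion`, `expected_discharge_m3` (one row per
#'   voyage), e.g. from [hindcast_voyages()].
#' @param distances Tibble with `src_port`, `dst_port`, `distance_nm`,
#'   e.g. from [port_distances()].
#' @param params A [decay_params()] object.
#' @param speed_knots Service speed used to turn distances into durations.
#' @return List of class `route_risk` with tibbles `routes` (per-route
#'   distance, duration, voyage count, volume and propagules), `sources`
#'   and `arrivals` (per-ecoregion totals), and `n_missing_distance`
#'   (voyages dropped for lack of a route distance).
#' @export
propagule_pressure <- function(hindcast_records, distances,
                               params = decay_params(), speed_knots = 15) {
  stopifnot(inherits(params, "decay_params"))
  h <- tibble::as_tibble(hindcast_records)
  req <- c("src_port", "dst_port", "src_ecoregion", "dst_ecoregion",
           "expected_discharge_m3")
  stopifnot(all(req %in% names(h)))
  h <- dplyr::left_join(h, distances, by = c("src_port", "dst_port"))
  n_missing <- sum(!is.finite(h$distance_nm))
  h <- dplyr::filter(h, is.finite(.data$distance_nm))
  h <- dplyr::mutate(h,
    duration_days = voyage_duration_days(.data$distance_nm, speed_knots),
    propagules = .data$expected_discharge_m3 *
      bwe_density(.data$duration_days, params))

  routes <- h |>
    dplyr::group_by(.data$src_port, .data$dst_port,
                    .data$src_ecoregion, .data$dst_ecoregion) |>
    dplyr::summarise(
      distance_nm = .data$distance_nm[1],
      duration_days = .data$duration_days[1],
      n_voyages = dplyr::n(),
      total_discharge_m3 = sum(.data$expected_discharge_m3),
      propagules = sum(.data$propagules),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$propagules),
                   dplyr::desc(.data$total_discharge_m3), .data$src_port)

  eco_sum <- function(key) {
    h |>
      dplyr::group_by(ecoregion = .data[[key]]) |>
      dplyr::summarise(n_voyages = dplyr::n(),
                       total_discharge_m3 = sum(.data$expected_discharge_m3),
                       propagules = sum(.data$propagules),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$propagules),
                     dplyr::desc(.data$total_discharge_m3), .data$ecoregion)
  }
  structure(list(routes = routes,
                 sources = eco_sum("src_ecoregion"),
                 arrivals = eco_sum("dst_ecoregion"),
                 params = params,
                 n_missing_distance = n_missing),
            class = "route_risk")
}

#' @export
print.route_risk <- function(x, ...) {
  cat(sprintf("<route_risk> %d routes, lambda-equivalent rate %.3f/day\n",
              nrow(x$routes),
              composite_lambda(x$params$mu1, x$params$mu2,
                               x$params$p_exchange)))
  print(utils::head(x$routes, 5))
  invisible(x)
}

#' Sensitivity of ecoregion rankings to the decay rate
#'
#' Re-ranks source and arrival ecoregions by total propagule pressure over
#' a grid of decay rates lambda (default 50 evenly spaced values on
#' \[0.01, 0.50\]). lambda = 0 is permitted as the no-decay baseline, under
#' which the ranking coincides with the ranking by total discharge volume.
#'
#' @inheritParams propagule_pressure
#' @param lambda_grid Numeric vector of decay rates (per day).
#' @return Object of class `sensitivity_grid`: a tibble `trajectories`
#'   with columns `lambda`, `side` ("source"/"arrival"), `ecoregion`,
#'   `propagules`, `rank` (1 = most important).
#' @export
sensitivity_rank <- function(hindcast_records, distances,
                             lambda_grid = seq(0.01, 0.50, length.out = 50),
                             params = decay_params(), speed_knots = 15) {
  if (length(lambda_grid) == 0) stop("empty lambda grid", call. = FALSE)
  if (any(lambda_grid < 0)) stop("lambda must be non-negative", call. = FALSE)
  traj <- purrr::map_dfr(lambda_grid, function(lam) {
    p <- decay_params(D0 = params$D0, lam = lam, mu1 = lam, mu2 = lam,
                      p_exchange = params$p_exchange, r = params$r)
    rr <- propagule_pressure(hindcast_records, distances, p, speed_knots)
    dplyr::bind_rows(
      dplyr::mutate(rr$sources, side = "source"),
      dplyr::mutate(rr$arrivals, side = "arrival")) |>
      dplyr::group_by(.data$side) |>
      dplyr::mutate(lambda = lam, rank = dplyr::row_number()) |>
      dplyr::ungroup()
  })
  structure(list(trajectories = traj, lambda_grid = lambda_grid),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("<sensitivity_grid> %d lambda values in [%.3g, %.3g], %d ecoregion-side series\n",
              length(x$lambda_grid), min(x$lambda_grid), max(x$lambda_grid),
              nrow(dplyr::distinct(x$trajectories, .data$side, .data$ecoregion))))
  invisible(x)
}

#' Top routes by a risk metric
#'
#' Ranks routes by voyage count, discharge volume or propagule pressure
#' and reports the share of the grand total covered by the top n. Ties are
#' broken by larger volume, then alphabetical source port id.
#'
#' @param route_risks A [propagule_pressure()] result, or its `routes`
#'   tibble.
#' @param metric One of "voyages", "volume", "propagules".
#' @param n Number of routes to keep.
#' @return Tibble of the top-n routes with a `metric_value` column; the
#'   covered fraction of the grand total is in attribute `share` and
#'   column `cumulative_share`.
#' @export
top_routes <- function(route_risks, metric = c("propagules", "volume",
                                               "voyages"), n = 20) {
  metric <- match.arg(metric)
  stopifnot(n >= 1)
  routes <- if (inherits(route_risks, "route_risk")) route_risks$routes
            else tibble::as_tibble(route_risks)
  col <- switch(metric, voyages = "n_voyages",
                volume = "total_discharge_m3", propagules = "propagules")
  total <- sum(routes[[col]])
  out <- routes |>
    dplyr::mutate(metric_value = .data[[col]]) |>
    dplyr::arrange(dplyr::desc(.data$metric_value),
                   dplyr::desc(.data$total_discharge_m3), .data$src_port) |>
    utils::head(n) |>
    dplyr::mutate(cumulative_share = cumsum(.data$metric_value) / total)
  attr(out, "share") <- sum(out$metric_value) / total
  out
}
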