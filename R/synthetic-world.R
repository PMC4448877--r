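#' Configuration of the synthetic shipping world
#'
#' Describes the geography generated by [gen_world()]: a lon/lat bounding
#' box containing `n_islands` synthetic landmasses and a set of marine
#' ecoregions, each holding `ports_per_ecoregion` ports placed in water.
#' Roughly half the ecoregions are flagged `"arrival"` (the coastal waters
#' receiving traffic) and the rest `"source"` (foreign waters that
#' originate voyages).
#'
#' @param n_ecoregions Number of ecoregions (>= 2).
#' @param ports_per_ecoregion Ports per ecoregion.
#' @param n_islands Number of synthetic landmasses (0 for open ocean).
#' @param bbox Named numeric: `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @param purpose_weights Named probability weights over the 11 port
#'   purpose categories; mining purposes are over-represented by default.
#' @param seed Integer seed; the world is deterministic given it.
#' @return A `world_config` object.
#' @export
world_config <- function(n_ecoregions = 6, ports_per_ecoregion = 3,
                         n_islands = 5,
                         bbox = c(lon_min = 100, lon_max = 170,
                                  lat_min = -45, lat_max = 10),
                         purpose_weights = NULL, seed = 1) {
  stopifnot(n_ecoregions >= 2, ports_per_ecoregion >= 1, n_islands >= 0)
  if (bbox["lon_max"] <= bbox["lon_min"] || bbox["lat_max"] <= bbox["lat_min"]) {
    stop("degenerate bounding box", call. = FALSE)
  }
  if (is.null(purpose_weights)) {
    purpose_weights <- c(iron_ore = 0.18, coal = 0.15, tankers = 0.08,
                         other_minerals = 0.08, timber = 0.05, grains = 0.08,
                         sugar = 0.04, imports = 0.08, general_cargo = 0.10,
                         variety = 0.10, unknown = 0.06)
  }
  stopifnot(length(purpose_weights) == 11, all(purpose_weights > 0))
  structure(list(n_ecoregions = n_ecoregions,
                 ports_per_ecoregion = ports_per_ecoregion,
                 n_islands = n_islands, bbox = bbox,
                 purpose_weights = purpose_weights / sum(purpose_weights),
                 seed = seed),
            class = "world_config")
}

#' The 11 port purpose categories
#'
#' Broad classifications of a port by the primary makeup of its traffic:
#' iron ore, coal, tankers (petroleum/LNG/liquid fuels), other
#' metals/minerals, timber, grains, sugar, imports, general cargo,
#' variety, and none-of-the-above/unknown.
#'
#' @return Character vector of the 11 category names.
#' @export
port_purposes <- function() {
  c("iron_ore", "coal", "tankers", "other_minerals", "timber", "grains",
    "sugar", "imports", "general_cargo", "variety", "unknown")
}

star_polygon <- function(cx, cy, r, nv) {
  ang <- sort(stats::runif(nv, 0, 2 * pi))
  rad <- r * stats::runif(nv, 0.7, 1)
  cbind(lon = cx + rad * cos(ang), lat = cy + rad * sin(ang))
}

#' Generate the synthetic world
#'
#' Draws `n_islands` simple star-shaped land polygons inside the bounding
#' box, lays out ecoregion centres, and places ports in water (rejection
#' sampling around each ecoregion centre, bounded retries). Port purposes
#' are drawn from the 11-category scheme with the configured weights.
#' Deterministic given the config seed.
#'
#' @param config A [world_config()].
#' @return List of class `world`: `shoreline` (list of polygon matrices),
#'   `ports` (tibble: port_id, ecoregion_id, lon, lat, purpose, role),
#'   `ecoregions` (tibble: ecoregion_id, code, role).
#' @export
gen_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  bb <- config$bbox
  shoreline <- list()
  if (config$n_islands > 0) {
    span <- min(bb["lon_max"] - bb["lon_min"], bb["lat_max"] - bb["lat_min"])
    for (i in seq_len(config$n_islands)) {
      r <- stats::runif(1, 0.04, 0.10) * span
      cx <- stats::runif(1, bb["lon_min"] + r, bb["lon_max"] - r)
      cy <- stats::runif(1, bb["lat_min"] + r, bb["lat_max"] - r)
      shoreline[[i]] <- star_polygon(cx, cy, r, sample(6:12, 1))
    }
  }
  n_arr <- ceiling(config$n_ecoregions / 2)
  ecoregions <- tibble::tibble(
    ecoregion_id = sprintf("E%02d", seq_len(config$n_ecoregions)),
    code = 100L + seq_len(config$n_ecoregions),
    role = rep(c("arrival", "source"),
               c(n_arr, config$n_ecoregions - n_arr)))

  centres <- cbind(
    stats::runif(config$n_ecoregions, bb["lon_min"], bb["lon_max"]),
    stats::runif(config$n_ecoregions, bb["lat_min"], bb["lat_max"]))
  ports <- purrr::map_dfr(seq_len(config$n_ecoregions), function(e) {
    purrr::map_dfr(seq_len(config$ports_per_ecoregion), function(k) {
      for (try in 1:200) {
        p <- centres[e, ] + stats::runif(2, -2.5, 2.5)
        p[1] <- min(max(p[1], bb["lon_min"]), bb["lon_max"])
        p[2] <- min(max(p[2], bb["lat_min"]), bb["lat_max"])
        if (!any(point_in_any_polygon(matrix(p, 1, 2), shoreline))) {
          return(tibble::tibble(
            port_id = sprintf("P%02d_%02d", e, k),
            ecoregion_id = ecoregions$ecoregion_id[e],
            lon = p[1], lat = p[2]))
        }
      }
      stop("could not place a port in water for ecoregion ",
           ecoregions$ecoregion_id[e], call. = FALSE)
    })
  })
  ports$purpose <- sample(names(config$purpose_weights), nrow(ports),
                          replace = TRUE, prob = config$purpose_weights)
  ports$role <- ecoregions$role[match(ports$ecoregion_id,
                                      ecoregions$ecoregion_id)]
  structure(list(shoreline = shoreline, ports = ports,
                 ecoregions = ecoregions, config = config),
            class = "world")
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf("<world> %d ecoregions, %d ports, %d islands\n",
              nrow(x$ecoregions), nrow(x$ports), length(x$shoreline)))
  invisible(x)
}

#' Fleet configuration
#'
#' Vessel counts, the probability mix over the four vessel classes
#' (bulker, tanker, container, other) and per-class truncated-normal
#' length distributions. Default lengths emulate an international cargo
#' fleet: bulkers and tankers around 220-225 m, container vessels around
#' 250 m, "other" (passenger, naval, general cargo, Ro-Ro, fishing, tugs)
#' much smaller; all lengths truncated to (30, 345] m.
#'
#' @param n_vessels Number of vessels.
#' @param type_mix Named probabilities over
#'   `c("bulker", "tanker", "container", "other")`, summing to 1.
#' @param length_params Tibble with `type`, `mean`, `sd`, `min`, `max` (m).
#' @return A `fleet_config` object.
#' @export
fleet_config <- function(n_vessels = 2000,
                         type_mix = c(bulker = 0.45, tanker = 0.20,
                                      container = 0.15, other = 0.20),
                         length_params = NULL) {
  stopifnot(n_vessels >= 1, abs(sum(type_mix) - 1) < 1e-8,
            all(type_mix >= 0),
            setequal(names(type_mix),
                     c("bulker", "tanker", "container", "other")))
  if (is.null(length_params)) {
    length_params <- tibble::tibble(
      type = c("bulker", "tanker", "container", "other"),
      mean = c(225, 220, 250, 120),
      sd = c(40, 45, 50, 50),
      min = 30, max = 345)
  }
  structure(list(n_vessels = n_vessels, type_mix = type_mix,
                 length_params = length_params),
            class = "fleet_config")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lo | out[bad] > hi]
  }
  out
}

#' Generate the vessel fleet
#'
#' @param config A [fleet_config()].
#' @param seed Integer seed.
#' @return Tibble with `vessel_id`, `type`, `length_m`.
#' @export
gen_fleet <- function(config = fleet_config(), seed = 1) {
  stopifnot(inherits(config, "fleet_config"))
  set.seed(seed)
  types <- sample(names(config$type_mix), config$n_vessels, replace = TRUE,
                  prob = config$type_mix)
  lp <- config$length_params
  len <- numeric(config$n_vessels)
  for (tp in unique(types)) {
    i <- which(types == tp)
    row <- lp[lp$type == tp, ]
    len[i] <- rtruncnorm(length(i), row$mean, row$sd, row$min, row$max)
  }
  tibble::tibble(vessel_id = sprintf("V%05d", seq_len(config$n_vessels)),
                 type = types, length_m = len)
}

#' Traffic configuration
#'
#' Annual voyage-count structure over the route network: a base expected
#' intensity per route-year, a multiplicative annual growth rate, and a
#' route-concentration parameter (gamma shape of per-route multipliers;
#' smaller values make a few routes dominate, as real traffic does).
#'
#' @param years Integer vector of study years.
#' @param base_intensity Expected voyages per route in the first year.
#' @param growth_rate Multiplicative annual growth in expected counts.
#' @param route_concentration Gamma shape of the mean-1 per-route
#'   intensity multiplier (negative-binomial route counts).
#' @param bulker_mining_boost Multiplier on the bulker type weight for
#'   voyages into mining-purpose (iron ore, coal) ports.
#' @return A `traffic_config` object.
#' @export
traffic_config <- function(years = 1999:2012, base_intensity = 2,
                           growth_rate = 1.06, route_concentration = 0.6,
                           bulker_mining_boost = 4) {
  stopifnot(length(years) >= 1, base_intensity > 0, growth_rate > 0,
            route_concentration > 0, bulker_mining_boost >= 1)
  structure(list(years = as.integer(years), base_intensity = base_intensity,
                 growth_rate = growth_rate,
                 route_concentration = route_concentration,
                 bulker_mining_boost = bulker_mining_boost),
            class = "traffic_config")
}

#' Generate the voyage history
#'
#' Routes run from every source-role port to every arrival-role port.
#' Per-route mean-1 gamma multipliers (shape `route_concentration`) times
#' the growing annual base intensity give Poisson voyage counts
#' (marginally negative-binomial). Each voyage is assigned a vessel, with
#' bulkers preferentially routed to mining-purpose destination ports.
#'
#' @param world A [gen_world()] result.
#' @param fleet A [gen_fleet()] table.
#' @param config A [traffic_config()].
#' @param seed Integer seed.
#' @return Tibble with `voyage_id`, `vessel_id`, `year`, `src_port`,
#'   `dst_port`.
#' @export
gen_voyages <- function(world, fleet, config = traffic_config(), seed = 1) {
  stopifnot(inherits(world, "world"), inherits(config, "traffic_config"))
  set.seed(seed)
  src <- world$ports$port_id[world$ports$role == "source"]
  dst <- world$ports$port_id[world$ports$role == "arrival"]
  stopifnot(length(src) > 0, length(dst) > 0)
  routes <- tidyr::expand_grid(src_port = src, dst_port = dst)
  routes$mult <- stats::rgamma(nrow(routes), shape = config$route_concentration,
                               rate = config$route_concentration)
  dst_purpose <- world$ports$purpose[match(routes$dst_port,
                                           world$ports$port_id)]
  mining <- dst_purpose %in% c("iron_ore", "coal")

  type_levels <- c("bulker", "tanker", "container", "other")
  type_w <- prop.table(table(factor(fleet$type, levels = type_levels)))
  vessels_by_type <- split(fleet$vessel_id,
                           factor(fleet$type, levels = type_levels))

  y0 <- min(config$years)
  out <- purrr::map_dfr(config$years, function(yr) {
    lam <- config$base_intensity * routes$mult *
      config$growth_rate^(yr - y0)
    counts <- stats::rpois(nrow(routes), lam)
    idx <- rep.int(seq_len(nrow(routes)), counts)
    if (length(idx) == 0) return(NULL)
    w <- matrix(rep(as.numeric(type_w), length(idx)), ncol = 4, byrow = TRUE)
    colnames(w) <- names(type_w)
    w[mining[idx], "bulker"] <- w[mining[idx], "bulker"] *
      config$bulker_mining_boost
    w <- w / rowSums(w)
    cum <- t(apply(w, 1, cumsum))
    u <- stats::runif(length(idx))
    ti <- 1L + rowSums(u > cum)
    tp <- colnames(w)[pmin(ti, 4L)]
    vid <- vapply(tp, function(t) {
      pool <- vessels_by_type[[t]]
      pool[sample.int(length(pool), 1)]
    }, character(1))
    tibble::tibble(year = yr, src_port = routes$src_port[idx],
                   dst_port = routes$dst_port[idx], vessel_id = vid)
  })
  out$voyage_id <- sprintf("J%06d", seq_len(nrow(out)))
  dplyr::select(out, "voyage_id", "vessel_id", "year", "src_port",
                "dst_port")
}

#' Ground-truth generative parameters for the ballast census
#'
#' The known parameters from which [gen_ballast_census()] draws discharge,
#' exchange timing, provenance mismatches and corrupt records; parameter
#' recovery against these values is the basis of the downstream tests.
#' Bulker discharge follows a 4-component mixture of linear regressions on
#' calculated ballast capacity (regimes from minimal to heavy-ballast
#' discharge); tanker/container/other discharge is linear in capacity with
#' destination-purpose offsets. BWE timing is Beta(8, 8) (mode mid-voyage).
#'
#' @param mixture List with `weights`, `beta1`, `beta2`, `sigma` (equal
#'   lengths; weights sum to 1).
#' @param linear Named list per vessel type (`tanker`, `container`,
#'   `other`), each with `intercept`, `slope`, `sigma` and `purpose_offsets`
#'   (named over [port_purposes()]).
#' @param exchange_position `c(a, b)` Beta shape parameters for BWE timing.
#' @param provenance_mismatch_rate Proportion of events whose uptake port
#'   differs from the voyage source.
#' @param mismatch_within_ecoregion Of mismatched events, the proportion
#'   drawn from another port in the same source ecoregion (nearby previous
#'   port of call), versus anywhere.
#' @param corruption_rate Proportion of ballast voyage records corrupted
#'   (invalid length, or infeasible discharge) to exercise curation.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(mixture = NULL, linear = NULL,
                         exchange_position = c(a = 8, b = 8),
                         provenance_mismatch_rate = 0.2,
                         mismatch_within_ecoregion = 0.5,
                         corruption_rate = 0.05) {
  if (is.null(mixture)) {
    mixture <- list(weights = c(0.25, 0.30, 0.30, 0.15),
                    beta1 = c(400, 1200, 800, 1500),
                    beta2 = c(0.05, 0.30, 0.60, 0.95),
                    sigma = c(250, 1200, 1800, 2200))
  }
  stopifnot(abs(sum(mixture$weights) - 1) < 1e-8,
            length(mixture$weights) == length(mixture$beta2))
  if (is.null(linear)) {
    off <- function(scale) {
      o <- scale * seq(-0.5, 0.5, length.out = 11)
      names(o) <- port_purposes()
      o
    }
    linear <- list(
      tanker = list(intercept = 900, slope = 0.35, sigma = 900,
                    purpose_offsets = off(1200)),
      container = list(intercept = 400, slope = 0.15, sigma = 600,
                       purpose_offsets = off(700)),
      other = list(intercept = 300, slope = 0.25, sigma = 500,
                   purpose_offsets = off(500)))
  }
  rates <- c(provenance_mismatch_rate, mismatch_within_ecoregion,
             corruption_rate)
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(list(mixture = mixture, linear = linear,
                 exchange_position = exchange_position,
                 provenance_mismatch_rate = provenance_mismatch_rate,
                 mismatch_within_ecoregion = mismatch_within_ecoregion,
                 corruption_rate = corruption_rate),
            class = "ground_truth")
}

#' Generate the ballast census
#'
#' Draws per-voyage ballast discharge from the type-specific ground-truth
#' model on calculated ballast capacity (negative draws truncated to 0),
#' splits each voyage total over 1-3 tank events, assigns a BWE position
#' from the Beta timing distribution, mismatches a fraction of uptake
#' ports against the voyage source, and corrupts a fraction of voyage
#' records (length 0, length > 345 m, or discharge above 120% of DWT)
#' after clean generation. Injected problems are flagged in
#' `injected_error` / `uptake_mismatch` so curation counts can be asserted
#' exactly.
#'
#' @param voyages A [gen_voyages()] table (or a subset, e.g. the census
#'   years).
#' @param world The [gen_world()] result.
#' @param fleet The [gen_fleet()] table.
#' @param truth A [ground_truth()] object.
#' @param seed Integer seed.
#' @param coeffs [design_coefficients()] used for capacity calculation.
#' @return Tibble of tank events: `event_id`, `voyage_id`, `vessel_id`,
#'   `vessel_type`, `year`, `tank`, `src_port`, `dst_port`, `uptake_port`,
#'   `discharge_port`, `src_ecoregion`, `dst_ecoregion`, `purpose`,
#'   `length_m`, `capacity_m3`, `volume_m3`, `exchange_position`,
#'   `uptake_mismatch`, `injected_error`.
#' @export
gen_ballast_census <- function(voyages, world, fleet,
                               truth = ground_truth(), seed = 1,
                               coeffs = design_coefficients()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(world, "world"))
  set.seed(seed)
  v <- dplyr::left_join(tibble::as_tibble(voyages),
                        dplyr::select(fleet, "vessel_id", "type",
                                      "length_m"),
                        by = "vessel_id")
  ports <- world$ports
  v$src_ecoregion <- ports$ecoregion_id[match(v$src_port, ports$port_id)]
  v$dst_ecoregion <- ports$ecoregion_id[match(v$dst_port, ports$port_id)]
  v$purpose <- ports$purpose[match(v$dst_port, ports$port_id)]
  v$capacity_m3 <- calc_ballast_capacity(calc_dwt(v$length_m, coeffs),
                                         coeffs)
  n <- nrow(v)

  # clean per-voyage discharge from the type-specific generative model
  y <- numeric(n)
  ib <- which(v$type == "bulker")
  if (length(ib)) {
    mx <- truth$mixture
    j <- sample.int(length(mx$weights), length(ib), replace = TRUE,
                    prob = mx$weights)
    y[ib] <- mx$beta1[j] + mx$beta2[j] * v$capacity_m3[ib] +
      stats::rnorm(length(ib), 0, mx$sigma[j])
  }
  for (tp in c("tanker", "container", "other")) {
    i <- which(v$type == tp)
    if (!length(i)) next
    g <- truth$linear[[tp]]
    y[i] <- g$intercept + g$purpose_offsets[v$purpose[i]] +
      g$slope * v$capacity_m3[i] + stats::rnorm(length(i), 0, g$sigma)
  }
  y <- pmax(y, 0)
  v$discharge_m3 <- y
  v$injected_error <- NA_character_

  # record-level corruption, injected after clean generation
  nc <- stats::rbinom(1, n, truth$corruption_rate)
  if (nc > 0) {
    ci <- sample.int(n, nc)
    kind <- sample(c("length_zero", "length_over", "discharge_infeasible"),
                   nc, replace = TRUE)
    v$injected_error[ci] <- kind
    v$length_m[ci[kind == "length_zero"]] <- 0
    v$length_m[ci[kind == "length_over"]] <-
      345 + stats::runif(sum(kind == "length_over"), 5, 60)
    di <- ci[kind == "discharge_infeasible"]
    dwt <- calc_dwt(v$length_m[di], coeffs)
    v$discharge_m3[di] <- dwt * stats::runif(length(di), 1.25, 1.6)
  }

  # split voyage totals over 1-3 tanks
  n_tanks <- sample.int(3, n, replace = TRUE)
  ev <- v[rep.int(seq_len(n), n_tanks), ]
  ev$tank <- unlist(lapply(n_tanks, seq_len), use.names = FALSE)
  frac <- stats::runif(nrow(ev), 0.2, 1)
  tot <- tapply(frac, rep.int(seq_len(n), n_tanks), sum)
  ev$volume_m3 <- as.numeric(ev$discharge_m3 * frac /
                               tot[rep.int(seq_len(n), n_tanks)])

  # provenance: uptake mostly at the source port; a fraction mismatched
  ne <- nrow(ev)
  ev$uptake_port <- ev$src_port
  ev$uptake_mismatch <- stats::runif(ne) < truth$provenance_mismatch_rate
  mi <- which(ev$uptake_mismatch)
  if (length(mi)) {
    near <- stats::runif(length(mi)) < truth$mismatch_within_ecoregion
    ev$uptake_port[mi] <- vapply(seq_along(mi), function(q) {
      i <- mi[q]
      pool <- if (near[q]) {
        setdiff(ports$port_id[ports$ecoregion_id == ev$src_ecoregion[i]],
                ev$src_port[i])
      } else {
        setdiff(ports$port_id, ev$src_port[i])
      }
      if (!length(pool)) pool <- setdiff(ports$port_id, ev$src_port[i])
      pool[sample.int(length(pool), 1)]
    }, character(1))
  }
  ev$discharge_port <- ev$dst_port
  ev$exchange_position <- stats::rbeta(ne, truth$exchange_position["a"],
                                       truth$exchange_position["b"])
  ev$event_id <- sprintf("B%07d", seq_len(ne))
  dplyr::select(ev, "event_id", "voyage_id", "vessel_id",
                vessel_type = "type", "year", "tank", "src_port",
                "dst_port", "uptake_port", "discharge_port",
                "src_ecoregion", "dst_ecoregion", "purpose", "length_m",
                "capacity_m3", "volume_m3", "exchange_position",
                "uptake_mismatch", "injected_error")
}

#' Sum tank events to per-voyage ballast totals
#'
#' Discharge models are per-journey, so tank events are summed to voyage
#' totals before curation and fitting.
#'
#' @param events A [gen_ballast_census()] table (or real census with the
#'   same columns).
#' @return Tibble with one row per voyage: identifiers, vessel type,
#'   length, capacity, destination purpose, ecoregions and total
#'   `discharge_m3`.
#' @export
census_voyage_totals <- function(events) {
  tibble::as_tibble(events) |>
    dplyr::group_by(.data$voyage_id) |>
    dplyr::summarise(
      vessel_id = .data$vessel_id[1],
      vessel_type = .data$vessel_type[1],
      year = .data$year[1],
      src_port = .data$src_port[1],
      dst_port = .data$dst_port[1],
      src_ecoregion = .data$src_ecoregion[1],
      dst_ecoregion = .data$dst_ecoregion[1],
      purpose = .data$purpose[1],
      length_m = .data$length_m[1],
      capacity_m3 = .data$capacity_m3[1],
      discharge_m3 = sum(.data$volume_m3),
      injected_error = .data$injected_error[1],
      .groups = "drop")
}
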