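# Shared fixtures and independent oracles, built in code at test time.

# ---- data generators -------------------------------------------------------

# bulker-like capacities from the fleet length distribution
gen_capacities <- function(n) {
  L <- stats::rnorm(n, 225, 40)
  bad <- which(L < 30 | L > 345)
  while (length(bad)) {
    L[bad] <- stats::rnorm(length(bad), 225, 40)
    bad <- bad[L[bad] < 30 | L[bad] > 345]
  }
  calc_ballast_capacity(calc_dwt(L))
}

# draws from a known mixture of regressions (the ground-truth defaults)
gen_mixture_data <- function(n, gt = ground_truth()$mixture, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- gen_capacities(n)
  j <- sample(length(gt$weights), n, TRUE, gt$weights)
  y <- pmax(gt$beta1[j] + gt$beta2[j] * x + stats::rnorm(n, 0, gt$sigma[j]),
            0)
  list(x = x, y = y, component = j, truth = gt)
}

# tanker-like linear data with purpose offsets
gen_tanker_data <- function(n, seed = NULL, sigma = 900) {
  if (!is.null(seed)) set.seed(seed)
  g <- ground_truth()$linear$tanker
  x <- gen_capacities(n)
  purpose <- sample(port_purposes(), n, TRUE)
  eco <- sample(sprintf("E%02d", 1:6), n, TRUE)
  port <- sample(sprintf("P%02d", 1:12), n, TRUE)
  y <- g$intercept + g$purpose_offsets[purpose] + g$slope * x +
    stats::rnorm(n, 0, sigma)
  tibble::tibble(discharge_m3 = pmax(y, 0), capacity_m3 = x,
                 purpose = purpose, src_ecoregion = eco,
                 dst_ecoregion = sample(eco), src_port = port,
                 dst_port = sample(port))
}

# a small self-consistent world + traffic + census
gen_small_study <- function(seed = 42, n_vessels = 300, years = 1999:2001,
                            truth = ground_truth(), n_islands = 2) {
  world <- gen_world(world_config(n_ecoregions = 4, ports_per_ecoregion = 2,
                                  n_islands = n_islands, seed = seed))
  fleet <- gen_fleet(fleet_config(n_vessels = n_vessels), seed = seed + 1)
  voyages <- gen_voyages(world, fleet,
                         traffic_config(years = years, base_intensity = 3),
                         seed = seed + 2)
  events <- gen_ballast_census(voyages, world, fleet, truth,
                               seed = seed + 3)
  list(world = world, fleet = fleet, voyages = voyages, events = events)
}

# ---- geometric oracles (independent of the package implementation) --------

# strict orientation test
.orient <- function(a, b, c) {
  sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
}

# proper (interior) crossing of segments p1-p2 and p3-p4
segments_cross <- function(p1, p2, p3, p4) {
  o1 <- .orient(p1, p2, p3)
  o2 <- .orient(p1, p2, p4)
  o3 <- .orient(p3, p4, p1)
  o4 <- .orient(p3, p4, p2)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

# brute-force oracle: does segment a-b cross into any polygon's interior?
oracle_segment_blocked <- function(a, b, polygons) {
  for (poly in polygons) {
    p <- as.matrix(poly)
    np <- nrow(p)
    for (i in seq_len(np)) {
      q1 <- p[i, ]
      q2 <- p[if (i == np) 1 else i + 1, ]
      if (segments_cross(a, b, q1, q2)) return(TRUE)
    }
    mid <- (a + b) / 2
    if (mgcv::in.out(p, matrix(mid, 1, 2))) return(TRUE)
  }
  FALSE
}

# exhaustive shortest path by enumerating all simple paths (tiny graphs)
oracle_shortest_path <- function(adj_w, src, dst) {
  n <- nrow(adj_w)
  best <- Inf
  visit <- function(v, dist, seen) {
    if (dist >= best) return()
    if (v == dst) { best <<- dist; return() }
    for (u in seq_len(n)) {
      if (!seen[u] && is.finite(adj_w[v, u])) {
        seen[u] <- TRUE
        visit(u, dist + adj_w[v, u], seen)
        seen[u] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n)
  seen[src] <- TRUE
  visit(src, 0, seen)
  best
}

# random archipelago world for routing tests; returns ports + polygons
gen_archipelago <- function(seed, n_ports = 8, n_islands = 3,
                            bbox = c(0, 12, -6, 6)) {
  set.seed(seed)
  polys <- lapply(seq_len(n_islands), function(i) {
    r <- stats::runif(1, 0.6, 1.4)
    cx <- stats::runif(1, bbox[1] + r, bbox[2] - r)
    cy <- stats::runif(1, bbox[3] + r, bbox[4] - r)
    nv <- sample(5:7, 1)
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    cbind(lon = cx + r * stats::runif(nv, 0.7, 1) * cos(ang),
          lat = cy + r * stats::runif(nv, 0.7, 1) * sin(ang))
  })
  ports <- NULL
  k <- 0
  while (k < n_ports) {
    p <- c(stats::runif(1, bbox[1], bbox[2]),
           stats::runif(1, bbox[3], bbox[4]))
    if (!any(vapply(polys, function(pg)
      mgcv::in.out(as.matrix(pg), matrix(p, 1, 2)), logical(1)))) {
      k <- k + 1
      ports <- rbind(ports, p)
    }
  }
  list(ports = tibble::tibble(port_id = sprintf("p%02d", seq_len(n_ports)),
                              lon = ports[, 1], lat = ports[, 2]),
       shoreline = polys)
}

# ---- misc ------------------------------------------------------------------

make_truth_models <- function(truth = ground_truth()) {
  gt <- truth$mixture
  ord <- order(gt$beta2)
  mix <- ballastr:::new_mixture(length(gt$weights), gt$weights[ord],
                                gt$beta1[ord], gt$beta2[ord], gt$sigma[ord],
                                ll <- 0, 1000, 0, 1L)
  lin <- lapply(truth$linear, function(g) {
    structure(list(
      predictors = c("capacity", "purpose"),
      intercept = g$intercept,
      capacity_slope = g$slope,
      factor_terms = list(purpose = tibble::tibble(
        level = names(g$purpose_offsets),
        offset = unname(g$purpose_offsets),
        freq = rep(1 / length(g$purpose_offsets),
                   length(g$purpose_offsets)))),
      sigma = g$sigma, loglik = NA_real_, n = NA_integer_, k = NA_integer_,
      bic = NA_real_, fitted_mean = NA_real_), class = "linear_discharge")
  })
  c(list(bulker = mix), lin)
}
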