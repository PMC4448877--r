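#' Great-circle distance in nautical miles
#'
#' Spherical great-circle distance with the sphere radius fixed by the
#' definition of the nautical mile: 1 nm = 1 arc-minute of great circle,
#' so the circumference is 360 * 60 = 21600 nm.
#'
#' @param a,b Numeric length-2 vectors `c(lon, lat)` in degrees, or
#'   two-column matrices of points.
#' @return Distance in nautical miles.
#' @examples
#' great_circle_nm(c(0, 0), c(0, 90))  # a quarter meridian: 5400 nm
#' @export
great_circle_nm <- function(a, b) {
  r_nm <- 21600 / (2 * pi)
  geosphere::distHaversine(normalize_lon(a), normalize_lon(b), r = r_nm)
}

normalize_lon <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  lon <- p[, 1]
  lon <- ((lon + 180) %% 360) - 180
  lon[lon == -180] <- 180  # longitudes live in (-180, 180]
  cbind(lon, p[, 2])
}

# Evenly spaced points on the lon/lat segment a-b, count 2^k + 1 with k
# chosen so spacing <= sampling_step (nm). Powers of two keep coarser
# sample sets nested inside finer ones, so refining the step can only
# block more edges, never fewer.
segment_samples <- function(a, b, sampling_step) {
  len <- great_circle_nm(a, b)
  k <- max(1, ceiling(log2(max(len / sampling_step, 1))))
  t <- seq(0, 1, length.out = 2^k + 1)
  t <- t[-c(1, length(t))]  # endpoints are known-water nodes
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
}

point_in_any_polygon <- function(pts, polygons) {
  if (length(polygons) == 0 || nrow(pts) == 0) {
    return(rep(FALSE, nrow(pts)))
  }
  inside <- rep(FALSE, nrow(pts))
  for (poly in polygons) {
    bnd <- as.matrix(poly)[, 1:2, drop = FALSE]
    todo <- !inside
    if (any(todo)) {
      inside[todo] <- mgcv::in.out(bnd, pts[todo, , drop = FALSE])
    }
  }
  inside
}

# Exact planar blocking test, vectorised over candidate segments a[i]-b[i]:
# blocked when the segment properly crosses a polygon side, or when its
# midpoint lies inside a polygon (segment wholly inside). Touching at a
# point does not block (strict orientation inequalities).
segment_blocked_exact <- function(a, b, polygons) {
  n <- nrow(a)
  blocked <- rep(FALSE, n)
  if (length(polygons) == 0 || n == 0) return(blocked)
  cross2 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  for (poly in polygons) {
    p <- as.matrix(poly)[, 1:2, drop = FALSE]
    np <- nrow(p)
    q1 <- p
    q2 <- p[c(seq_len(np - 1) + 1, 1), , drop = FALSE]
    todo <- which(!blocked)
    if (!length(todo)) break
    for (j in seq_len(np)) {
      o1 <- cross2(a[todo, 1], a[todo, 2], b[todo, 1], b[todo, 2],
                   q1[j, 1], q1[j, 2])
      o2 <- cross2(a[todo, 1], a[todo, 2], b[todo, 1], b[todo, 2],
                   q2[j, 1], q2[j, 2])
      o3 <- cross2(q1[j, 1], q1[j, 2], q2[j, 1], q2[j, 2],
                   a[todo, 1], a[todo, 2])
      o4 <- cross2(q1[j, 1], q1[j, 2], q2[j, 1], q2[j, 2],
                   b[todo, 1], b[todo, 2])
      hit <- (o1 * o2 < 0) & (o3 * o4 < 0)
      blocked[todo[hit]] <- TRUE
      todo <- todo[!hit]
      if (!length(todo)) break
    }
    if (length(todo)) {
      mid <- (a[todo, , drop = FALSE] + b[todo, , drop = FALSE]) / 2
      inside <- mgcv::in.out(p, mid)
      blocked[todo[inside]] <- TRUE
    }
  }
  blocked
}

# Nudge each polygon vertex outward along the bisector normal so that
# navigation nodes sit just offshore of the landmass they trace.
offset_polygon_vertices <- function(poly, offset_deg) {
  p <- as.matrix(poly)[, 1:2, drop = FALSE]
  n <- nrow(p)
  prev <- p[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- p[c(seq_len(n - 1) + 1, 1), , drop = FALSE]
  # outward = away from the polygon centroid along the angle bisector
  ctr <- colMeans(p)
  dir <- p - matrix(ctr, n, 2, byrow = TRUE)
  nrm <- sqrt(rowSums(dir^2))
  nrm[nrm == 0] <- 1
  p + offset_deg * dir / nrm
}

#' Build the over-water visibility graph
#'
#' Constructs an undirected graph on ports plus shoreline vertices in which
#' an edge joins two nodes whenever the straight lon/lat segment between
#' them never enters the interior of a land polygon. Edge weights are
#' great-circle distances in nautical miles. Shoreline vertices are nudged
#' offshore by `vertex_offset_deg` so navigation nodes never sit exactly on
#' a land boundary.
#'
#' Two land tests are available. `"crossing"` (default) is exact in the
#' lon/lat plane: an edge is blocked when its segment properly crosses a
#' polygon side or its midpoint lies inside a polygon. `"sampled"` tests
#' points placed densely along the segment (spacing at most
#' `sampling_step` nm, counts of the form 2^k + 1 so that refining the
#' step only ever blocks more edges, never fewer); it can miss crossings
#' whose inside chord is shorter than the step, e.g. grazing contacts near
#' shoreline corners.
#'
#' @param shoreline List of land polygons; each polygon a matrix or data
#'   frame with lon, lat columns (degrees), simple and implicitly closed.
#'   Polygons crossing the antimeridian must be pre-split.
#' @param ports Data frame with columns `port_id`, `lon`, `lat`; every port
#'   must lie in water.
#' @param sampling_step Sampling interval along candidate edges, nm
#'   (`land_test = "sampled"` only).
#' @param vertex_offset_deg Offshore nudge applied to shoreline vertices.
#' @param land_test `"crossing"` (exact planar) or `"sampled"`.
#' @return An object of class `water_graph`: list with the `igraph` graph,
#'   a node table and the shoreline.
#' @export
build_water_graph <- function(shoreline, ports, sampling_step = 5,
                              vertex_offset_deg = 0.01,
                              land_test = c("crossing", "sampled")) {
  stopifnot(sampling_step > 0)
  land_test <- match.arg(land_test)
  ports <- tibble::as_tibble(ports)
  stopifnot(all(c("port_id", "lon", "lat") %in% names(ports)))

  port_xy <- normalize_lon(as.matrix(ports[, c("lon", "lat")]))
  bad <- point_in_any_polygon(port_xy, shoreline)
  if (any(bad)) {
    stop("port(s) on land: ", paste(ports$port_id[bad], collapse = ", "),
         call. = FALSE)
  }

  shore_xy <- NULL
  if (length(shoreline) > 0) {
    shore_xy <- do.call(rbind, lapply(shoreline, offset_polygon_vertices,
                                      offset_deg = vertex_offset_deg))
  }
  nodes <- tibble::tibble(
    node_id = c(as.character(ports$port_id),
                if (!is.null(shore_xy)) paste0(".shore", seq_len(nrow(shore_xy)))),
    lon = c(port_xy[, 1], if (!is.null(shore_xy)) shore_xy[, 1]),
    lat = c(port_xy[, 2], if (!is.null(shore_xy)) shore_xy[, 2]),
    is_port = c(rep(TRUE, nrow(ports)),
                rep(FALSE, if (is.null(shore_xy)) 0 else nrow(shore_xy)))
  )

  n <- nrow(nodes)
  xy <- as.matrix(nodes[, c("lon", "lat")])
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (land_test == "crossing") {
    keep <- !segment_blocked_exact(xy[pairs[, 1], , drop = FALSE],
                                   xy[pairs[, 2], , drop = FALSE],
                                   shoreline)
  } else {
    keep <- logical(nrow(pairs))
    for (e in seq_len(nrow(pairs))) {
      a <- xy[pairs[e, 1], ]
      b <- xy[pairs[e, 2], ]
      s <- segment_samples(a, b, sampling_step)
      keep[e] <- !any(point_in_any_polygon(s, shoreline))
    }
  }
  edges <- pairs[keep, , drop = FALSE]
  w <- great_circle_nm(xy[edges[, 1], , drop = FALSE],
                       xy[edges[, 2], , drop = FALSE])
  g <- igraph::graph_from_data_frame(
    data.frame(from = nodes$node_id[edges[, 1]],
               to = nodes$node_id[edges[, 2]],
               weight = w),
    directed = FALSE,
    vertices = as.data.frame(nodes))
  structure(list(graph = g, nodes = nodes, shoreline = shoreline,
                 sampling_step = sampling_step),
            class = "water_graph")
}

#' @export
print.water_graph <- function(x, ...) {
  cat(sprintf("<water_graph> %d nodes (%d ports), %d over-water edges\n",
              nrow(x$nodes), sum(x$nodes$is_port),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Shortest over-water path between two ports
#'
#' Minimal-weight path on the visibility graph. The distance is never less
#' than the direct great-circle distance. Unreachable destinations are
#' reported with distance `Inf` and an empty path.
#'
#' @param graph A [build_water_graph()] result.
#' @param src_port,dst_port Port ids present in the graph.
#' @return List with `distance_nm` and `path` (character vector of node ids).
#' @export
shortest_path_nm <- function(graph, src_port, dst_port) {
  stopifnot(inherits(graph, "water_graph"))
  ids <- graph$nodes$node_id
  if (!src_port %in% ids) stop("unknown port: ", src_port, call. = FALSE)
  if (!dst_port %in% ids) stop("unknown port: ", dst_port, call. = FALSE)
  d <- igraph::distances(graph$graph, v = src_port, to = dst_port)[1, 1]
  if (!is.finite(d)) {
    return(list(distance_nm = Inf, path = character(0)))
  }
  p <- igraph::shortest_paths(graph$graph, from = src_port, to = dst_port,
                              output = "vpath")$vpath[[1]]
  list(distance_nm = unname(d), path = names(p))
}

#' All-pairs port distance table
#'
#' Computes over-water shortest-path distances between every pair of ports
#' on the visibility graph, as a long tibble suitable for joining to
#' routes.
#'
#' @param graph A [build_water_graph()] result.
#' @return Tibble with `src_port`, `dst_port`, `distance_nm`.
#' @export
port_distances <- function(graph) {
  stopifnot(inherits(graph, "water_graph"))
  pids <- graph$nodes$node_id[graph$nodes$is_port]
  m <- igraph::distances(graph$graph, v = pids, to = pids)
  tibble::tibble(
    src_port = rep(rownames(m), times = ncol(m)),
    dst_port = rep(colnames(m), each = nrow(m)),
    distance_nm = as.vector(m)
  )
}

#' Voyage duration from distance
#'
#' Converts an over-water distance to a voyage duration assuming a fixed
#' service speed (default 15 knots, i.e. 360 nm per day).
#'
#' @param distance_nm Distance in nautical miles, non-negative.
#' @param speed_knots Speed in knots, strictly positive.
#' @return Duration in days.
#' @examples
#' voyage_duration_days(5400)  # 15 days at 15 knots
#' @export
voyage_duration_days <- function(distance_nm, speed_knots = 15) {
  if (any(speed_knots <= 0)) stop("speed must be positive", call. = FALSE)
  if (any(distance_nm < 0, na.rm = TRUE)) {
    stop("distance must be non-negative", call. = FALSE)
  }
  distance_nm / (speed_knots * 24)
}
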