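# mode_builders: the three mode-specific travel networks — driving (roads),
# walking (sidewalks + trails + pathways + generated crosswalks), and
# multimodal (walking plus bus routes and train lines entered at stops).

#' Build the driving network
#'
#' @param roads A [geo_segments()] layer with `mode = "road"`; every
#'   `class_label` must resolve through `speeds` (directly or via aliases).
#' @param speeds A [speed_map()].
#' @param snap_tol_m Endpoint merge tolerance.
#' @return A `travel_network` with class-specific edge speeds.
#' @export
build_road_network <- function(roads, speeds = speed_map(), snap_tol_m = 0.5) {
  roads <- resolve_segment_speeds(roads, speeds)
  build_graph(roads, snap_tol_m = snap_tol_m)
}

#' Build the walking network
#'
#' Merges sidewalks, trails, pathways, and crosswalk arcs into one network
#' at the constant walking speed. Sidewalk/trail/pathway polylines are split
#' wherever a crosswalk arc ends on them, so that endpoint-connectivity graph
#' building joins the crossings to the blocks they serve.
#'
#' @param sidewalks A [geo_segments()] layer.
#' @param crosswalks Output of [generate_crosswalks()] (or `NULL`).
#' @param trails,pathways Optional additional walkable layers.
#' @param speeds A [speed_map()]; only `walking_kmh` is used.
#' @param snap_tol_m Endpoint merge tolerance.
#' @return A `travel_network` whose edges all use the walking speed.
#' @export
build_walk_network <- function(sidewalks, crosswalks = NULL, trails = NULL,
                               pathways = NULL, speeds = speed_map(),
                               snap_tol_m = 0.5) {
  walkable <- bind_segments(sidewalks, trails, pathways)
  if (!is.null(crosswalks) && nrow(crosswalks) > 0L) {
    ends <- segment_endpoints(crosswalks)
    walkable <- split_segments_at_points(walkable, ends, tol = 1e-6)
    walkable <- bind_segments(walkable, crosswalks)
  }
  walkable$speed_kmh <- speeds$walking_kmh
  build_graph(walkable, snap_tol_m = snap_tol_m)
}

#' Bundle transit geometry
#'
#' @param routes [geo_segments()] with mode `"bus"` or `"train"`.
#' @param stops Data frame with columns `id`, `x`, `y`, `route_id` (bus
#'   stops). May be `NULL`/empty.
#' @param stations Data frame with the same columns (train stations).
#' @return An object of class `transit_layer`.
#' @export
transit_layer <- function(routes, stops = NULL, stations = NULL) {
  empty <- data.frame(id = character(), x = numeric(), y = numeric(),
                      route_id = character(), stringsAsFactors = FALSE)
  stops <- stops %||% empty
  stations <- stations %||% empty
  for (df in list(stops, stations)) {
    if (nrow(df) && !all(c("id", "x", "y", "route_id") %in% names(df)))
      stopf("stops/stations need columns id, x, y, route_id")
  }
  structure(list(routes = routes, stops = stops, stations = stations),
            class = "transit_layer")
}

# arc-length position of a point on a polyline, or NULL if farther than tol
polyline_position <- function(m, px, py, tol) {
  seglen <- sqrt(rowSums(diff(m)^2))
  cum <- c(0, cumsum(seglen))
  best <- NULL
  for (k in seq_len(nrow(m) - 1L)) {
    pr <- point_segment_projection(px, py, m[k, 1L], m[k, 2L],
                                   m[k + 1L, 1L], m[k + 1L, 2L])
    if (pr$dist <= tol && (is.null(best) || pr$dist < best$dist))
      best <- list(dist = pr$dist, s = cum[k] + pr$t * seglen[k])
  }
  best
}

#' Build the multimodal (walking + transit) network
#'
#' Adds bus and train edges on top of an existing walking network. Each
#' route polyline is split at its stops/stations; the pieces between
#' consecutive stops become transit edges timed at the route's speed (its
#' class speed when resolvable, otherwise the bus/train default). Every stop
#' and station becomes a node connected to the nearest walking node by a
#' `link` edge at walking speed plus an optional boarding penalty, so transit
#' can only be entered and left at stops. The walking network is contained
#' unchanged (same node ids and edges).
#'
#' @param walk A walking `travel_network` from [build_walk_network()].
#' @param transit A [transit_layer()].
#' @param speeds A [speed_map()].
#' @param boarding_penalty_min Minutes added to every link edge (default 0).
#' @param link_max_dist_m Maximum stop-to-sidewalk snap distance; a stop
#'   farther than this from every walking node is a data error.
#' @param stop_route_tol_m Maximum distance of a stop from its route polyline.
#' @return A `travel_network`; attribute `walk_node_ids` holds the node ids
#'   of the embedded walking network.
#' @export
build_multimodal_network <- function(walk, transit, speeds = speed_map(),
                                     boarding_penalty_min = 0,
                                     link_max_dist_m = 100,
                                     stop_route_tol_m = 1) {
  stopifnot(inherits(walk, "travel_network"), inherits(transit, "transit_layer"))
  check_number(boarding_penalty_min, "boarding_penalty_min", 0)
  nodes <- walk$nodes
  edges <- walk$edges
  next_id <- max(nodes$id) + 1L
  stop_tbl <- rbind(transit$stops, transit$stations)
  routes <- transit$routes
  # transit nodes are shared between routes when stops coincide (transfers)
  tn_env <- new.env(hash = TRUE, parent = emptyenv())
  tnode <- function(x, y) {
    key <- paste(round(x, 3), round(y, 3))
    id <- tn_env[[key]]
    if (is.null(id)) {
      id <- next_id
      next_id <<- next_id + 1L
      nodes <<- rbind(nodes, data.frame(id = id, x = x, y = y))
      tn_env[[key]] <- id
    }
    id
  }
  stop_node <- integer(nrow(stop_tbl))
  for (ri in seq_len(nrow(routes))) {
    m <- routes$coords[[ri]]
    rid <- routes$id[ri]
    rmode <- routes$mode[ri]
    speed <- if (!is.na(routes$speed_kmh[ri])) routes$speed_kmh[ri] else
      resolve_speed(speeds, routes$class_label[ri], rmode)
    on_route <- which(stop_tbl$route_id == rid)
    if (!length(on_route)) next
    pos <- numeric(length(on_route))
    for (j in seq_along(on_route)) {
      st <- stop_tbl[on_route[j], ]
      pp <- polyline_position(m, st$x, st$y, stop_route_tol_m)
      if (is.null(pp))
        stopf("stop '%s' does not lie on route '%s' (within %g m)",
              st$id, rid, stop_route_tol_m)
      pos[j] <- pp$s
    }
    ord <- order(pos)
    on_route <- on_route[ord]; pos <- pos[ord]
    node_ids <- vapply(on_route, function(j)
      tnode(stop_tbl$x[j], stop_tbl$y[j]), integer(1))
    stop_node[on_route] <- node_ids
    if (length(on_route) >= 2L) {
      for (j in seq_len(length(on_route) - 1L)) {
        len <- pos[j + 1L] - pos[j]
        if (len <= 1e-9) next
        edges <- rbind(edges, data.frame(
          u = node_ids[j], v = node_ids[j + 1L],
          time_min = distance_to_time(len, speed),
          mode = rmode, length_m = len,
          segment_id = sprintf("%s@%d", rid, j),
          stringsAsFactors = FALSE))
      }
    }
  }
  # link every stop/station to the nearest walking node
  walk_ids <- walk$nodes$id
  linked <- logical(next_id)  # avoid duplicate links for shared nodes
  for (j in seq_len(nrow(stop_tbl))) {
    nid <- stop_node[j]
    if (nid == 0L || linked[nid]) next
    linked[nid] <- TRUE
    target <- snap_point(walk, c(stop_tbl$x[j], stop_tbl$y[j]),
                         max_dist_m = link_max_dist_m)
    if (is.na(target))
      stopf("stop '%s' has no walking node within %g m", stop_tbl$id[j],
            link_max_dist_m)
    d <- sqrt((stop_tbl$x[j] - walk$nodes$x[match(target, walk_ids)])^2 +
              (stop_tbl$y[j] - walk$nodes$y[match(target, walk_ids)])^2)
    edges <- rbind(edges, data.frame(
      u = nid, v = target,
      time_min = distance_to_time(d, speeds$walking_kmh) +
        boarding_penalty_min,
      mode = "link", length_m = d,
      segment_id = sprintf("link_%s", stop_tbl$id[j]),
      stringsAsFactors = FALSE))
  }
  out <- structure(list(nodes = nodes, edges = edges),
                   class = "travel_network")
  attr(out, "walk_node_ids") <- walk_ids
  out
}
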