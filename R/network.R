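# network_core: travel-time graphs and shortest-path service areas.

#' Convert a distance to a travel time
#'
#' @param length_m Distance in metres (vectorized, `>= 0`).
#' @param speed_kmh Speed in km/h (vectorized, `> 0`).
#' @return Travel time in minutes: `length_m / (speed_kmh * 1000 / 60)`.
#' @examples
#' distance_to_time(4800, 4.8)  # one hour of walking
#' distance_to_time(1000, 50)   # 1.2 min along a Collector road
#' @export
distance_to_time <- function(length_m, speed_kmh) {
  if (!is.numeric(speed_kmh) || any(!is.finite(speed_kmh)) ||
      any(speed_kmh <= 0))
    stopf("`speed_kmh` must be positive and finite")
  if (!is.numeric(length_m) || any(!is.finite(length_m)) || any(length_m < 0))
    stopf("`length_m` must be non-negative and finite")
  length_m / (speed_kmh * 1000 / 60)
}

# Assign endpoint coordinates to node ids, merging points closer than tol.
# Deterministic in input order; grid-hash so it scales linearly.
snap_endpoints <- function(pts, tol) {
  n <- nrow(pts)
  assign_id <- integer(n)
  if (tol <= 0) {
    key <- paste(sprintf("%.9f", pts[, 1L]), sprintf("%.9f", pts[, 2L]))
    ids <- match(key, unique(key))
    return(list(assign = ids,
                coords = pts[!duplicated(key), , drop = FALSE]))
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  node_x <- numeric(n); node_y <- numeric(n); n_nodes <- 0L
  for (i in seq_len(n)) {
    x <- pts[i, 1L]; y <- pts[i, 2L]
    cx <- floor(x / tol); cy <- floor(y / tol)
    found <- 0L
    for (dx in -1:1) {
      for (dy in -1:1) {
        key <- paste(cx + dx, cy + dy)
        cand <- env[[key]]
        if (!is.null(cand)) {
          for (id in cand) {
            if ((x - node_x[id])^2 + (y - node_y[id])^2 <= tol^2) {
              found <- id; break
            }
          }
        }
        if (found) break
      }
      if (found) break
    }
    if (!found) {
      n_nodes <- n_nodes + 1L
      found <- n_nodes
      node_x[found] <- x; node_y[found] <- y
      key <- paste(cx, cy)
      env[[key]] <- c(env[[key]], found)
    }
    assign_id[i] <- found
  }
  list(assign = assign_id,
       coords = cbind(node_x[seq_len(n_nodes)], node_y[seq_len(n_nodes)]))
}

#' Build a travel-time network from segments
#'
#' One node per distinct segment endpoint (endpoints closer than `snap_tol_m`
#' are merged), one undirected edge per segment, weighted by
#' [distance_to_time()]. Connectivity is by endpoints only: segments that
#' cross mid-line without sharing an endpoint are not joined (split them
#' first, e.g. with [split_segments_at_points()]).
#'
#' @param segments A [geo_segments()] layer with all speeds resolved.
#' @param snap_tol_m Endpoint merge tolerance in metres.
#' @return An object of class `travel_network`: list with `nodes` (data frame
#'   `id`, `x`, `y`) and `edges` (data frame `u`, `v`, `time_min`, `mode`,
#'   `length_m`, `segment_id`).
#' @export
build_graph <- function(segments, snap_tol_m = 0.5) {
  check_number(snap_tol_m, "snap_tol_m", 0)
  if (nrow(segments) == 0L) stopf("no segments to build a network from")
  unresolved <- is.na(segments$speed_kmh)
  if (any(unresolved))
    stopf("unresolved speed for class(es): %s",
          paste(unique(segments$class_label[unresolved]), collapse = ", "))
  pts <- segment_endpoints(segments)
  sn <- snap_endpoints(pts, snap_tol_m)
  n_seg <- nrow(segments)
  u <- sn$assign[2L * seq_len(n_seg) - 1L]
  v <- sn$assign[2L * seq_len(n_seg)]
  time_min <- distance_to_time(segments$length_m, segments$speed_kmh)
  loops <- u == v
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop segment(s): %s", sum(loops),
                    paste(utils::head(segments$id[loops], 5L),
                          collapse = ", ")),
            call. = FALSE)
  }
  edges <- data.frame(u = u[!loops], v = v[!loops],
                      time_min = time_min[!loops],
                      mode = segments$mode[!loops],
                      length_m = segments$length_m[!loops],
                      segment_id = segments$id[!loops],
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = seq_len(nrow(sn$coords)),
                      x = sn$coords[, 1L], y = sn$coords[, 2L])
  structure(list(nodes = nodes, edges = edges), class = "travel_network")
}

#' @export
print.travel_network <- function(x, ...) {
  cat(sprintf("<travel_network> %d nodes, %d edges, %d component(s), %.1f km\n",
              nrow(x$nodes), nrow(x$edges), n_components(x),
              sum(x$edges$length_m) / 1000))
  invisible(x)
}

as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(network$edges$u),
               to = as.character(network$edges$v)),
    directed = FALSE,
    vertices = data.frame(name = as.character(network$nodes$id)))
  igraph::E(g)$weight <- network$edges$time_min
  g
}

#' Number of connected components of a travel network
#' @param network A `travel_network`.
#' @return Integer component count.
#' @export
n_components <- function(network) {
  igraph::components(as_igraph(network))$no
}

#' Snap a point to the nearest network node
#'
#' Nearest node by Euclidean distance; ties broken by the smallest node id.
#'
#' @param network A `travel_network`.
#' @param point Numeric length-2 vector (x, y) in metres.
#' @param max_dist_m Maximum snap distance; `NA` is returned when no node is
#'   within it.
#' @param node_ids Optional subset of node ids to snap to (e.g. walking nodes
#'   of a multimodal network).
#' @return Integer node id, or `NA_integer_`.
#' @export
snap_point <- function(network, point, max_dist_m = Inf, node_ids = NULL) {
  nodes <- network$nodes
  if (!is.null(node_ids)) nodes <- nodes[nodes$id %in% node_ids, ]
  if (nrow(nodes) == 0L) stopf("network has no nodes to snap to")
  d2 <- (nodes$x - point[1L])^2 + (nodes$y - point[2L])^2
  best <- order(d2, nodes$id)[1L]
  if (sqrt(d2[best]) > max_dist_m) return(NA_integer_)
  nodes$id[best]
}

#' Shortest travel times from one node to all nodes within a cutoff
#'
#' Label-setting (Dijkstra) shortest paths over the `time_min` edge weights.
#' The cutoff is inclusive (a node exactly at the cutoff is inside the
#' service area, with a 1e-9 minute tolerance for floating-point times).
#'
#' @param network A `travel_network`.
#' @param source Node id present in the network.
#' @param cutoff_min Service-area threshold in minutes (default 30).
#' @return Named numeric vector of minutes, names are node ids; contains the
#'   source at 0.
#' @export
one_to_many_times <- function(network, source, cutoff_min = 30) {
  check_number(cutoff_min, "cutoff_min", 0, strict = TRUE)
  if (!source %in% network$nodes$id) stopf("unknown source node '%s'", source)
  g <- as_igraph(network)
  d <- igraph::distances(g, v = as.character(source),
                         weights = igraph::E(g)$weight)[1L, ]
  d <- d[is.finite(d) & d <= cutoff_min + 1e-9]
  d
}

#' Travel-time matrix between two node sets
#'
#' @param network A `travel_network`.
#' @param from,to Vectors of node ids.
#' @return Matrix of minutes (`Inf` when unreachable), rows `from`,
#'   columns `to`.
#' @export
travel_time_matrix <- function(network, from, to) {
  g <- as_igraph(network)
  uf <- unique(from); ut <- unique(to)
  m <- igraph::distances(g, v = as.character(uf), to = as.character(ut),
                         weights = igraph::E(g)$weight)
  m <- m[match(from, uf), match(to, ut), drop = FALSE]
  dimnames(m) <- list(as.character(from), as.character(to))
  m
}

#' Write a network as a node/edge CSV pair
#'
#' @param network A `travel_network`.
#' @param nodes_path,edges_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_network_csv <- function(network, nodes_path, edges_path) {
  utils::write.csv(network$nodes, nodes_path, row.names = FALSE)
  utils::write.csv(network$edges, edges_path, row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
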