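# Shared fixtures and independent oracles for the test suite.

# --- independent shortest-path oracle: exhaustive simple-path enumeration ---
# Returns the minimum total time from `source` to every node over all simple
# paths, as a named vector (unreachable nodes absent). Usable only on tiny
# graphs.
brute_shortest_times <- function(network, source, cutoff_min = Inf) {
  ids <- network$nodes$id
  best <- stats::setNames(rep(Inf, length(ids)), as.character(ids))
  adj <- lapply(ids, function(i) {
    e <- network$edges
    rbind(data.frame(to = e$v[e$u == i], w = e$time_min[e$u == i]),
          data.frame(to = e$u[e$v == i], w = e$time_min[e$v == i]))
  })
  names(adj) <- as.character(ids)
  walk <- function(node, t, visited) {
    key <- as.character(node)
    if (t < best[[key]]) best[[key]] <<- t
    nb <- adj[[key]]
    for (r in seq_len(nrow(nb))) {
      nxt <- nb$to[r]
      if (!(nxt %in% visited)) walk(nxt, t + nb$w[r], c(visited, nxt))
    }
  }
  walk(source, 0, source)
  best[is.finite(best) & best <= cutoff_min + 1e-9]
}

# random small multigraph as a travel_network (via segments, so the same
# construction path as production use); speeds 60 km/h so time = length/1000
random_small_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  # coordinates far apart so endpoint snapping cannot merge nodes
  coords <- cbind(sample.int(1000, n_nodes) * 10, sample.int(1000, n_nodes) * 10)
  u <- sample.int(n_nodes, n_edges, replace = TRUE)
  v <- sample.int(n_nodes, n_edges, replace = TRUE)
  keep <- u != v
  u <- u[keep]; v <- v[keep]
  if (!length(u)) { u <- 1L; v <- 2L }
  lens <- stats::runif(length(u), 100, 5000)
  segs <- lapply(seq_along(u), function(k) {
    m <- rbind(coords[u[k], ], coords[v[k], ])
    # give parallel edges distinct lengths via a midpoint detour
    mid <- colMeans(m) + c(0, lens[k] / 10)
    rbind(m[1, ], mid, m[2, ])
  })
  build_graph(geo_segments(segs, mode = "road", class_label = "X",
                           speed_kmh = 60,
                           id = sprintf("e%d", seq_along(segs))),
              snap_tol_m = 0.5)
}

# Moran's I by direct double-sum over the dense weights matrix
brute_moran <- function(y, W) {
  Wm <- weights_matrix(W)
  z <- y - mean(y)
  n <- length(y)
  (n / sum(Wm)) * sum(Wm * outer(z, z)) / sum(z^2)
}

# proper segment-segment intersection by orientation tests (touching counts)
segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  (o1 != o2 && o3 != o4) ||
    (o1 == 0 && o2 == 0 &&
       max(min(p1[1], p2[1]), min(q1[1], q2[1])) <=
         min(max(p1[1], p2[1]), max(q1[1], q2[1])) &&
       max(min(p1[2], p2[2]), min(q1[2], q2[2])) <=
         min(max(p1[2], p2[2]), max(q1[2], q2[2])))
}

# --- canonical 4-way crossing fixture ------------------------------------
# One road intersection at the origin, sidewalk rings of the four abutting
# blocks reaching into the 18-m buffer (8 circle crossings).
fourway_fixture <- function() {
  roads <- geo_segments(
    list(cbind(c(0, 0), c(-100, 100)), cbind(c(-100, 100), c(0, 0))),
    mode = "road", class_label = "Collector", id = c("rv", "rh"))
  sw <- list()
  for (sx in c(-1, 1)) {
    for (sy in c(-1, 1)) {
      sw[[length(sw) + 1L]] <- cbind(c(sx * 6, sx * 100), c(sy * 6, sy * 6))
      sw[[length(sw) + 1L]] <- cbind(c(sx * 6, sx * 6), c(sy * 6, sy * 100))
    }
  }
  list(roads = roads,
       sidewalks = geo_segments(sw, mode = "sidewalk",
                                id = sprintf("sw%d", seq_along(sw))),
       intersections = cbind(x = 0, y = 0))
}

# --- memoised small synthetic cities (shared across test files) ----------
.city_cache <- new.env(parent = emptyenv())
cached_city <- function(blocks = 8, seed = 7) {
  key <- sprintf("b%d_s%d", blocks, seed)
  if (is.null(.city_cache[[key]]))
    .city_cache[[key]] <- generate_city(
      city_config(blocks_per_side = blocks, seed = seed))
  .city_cache[[key]]
}
cached_run <- function(blocks = 8, seed = 7) {
  key <- sprintf("run_b%d_s%d", blocks, seed)
  if (is.null(.city_cache[[key]]))
    .city_cache[[key]] <- run_pipeline(cached_city(blocks, seed),
                                       seed = 1, n_perm = 199)
  .city_cache[[key]]
}
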