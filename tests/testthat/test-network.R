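test_that("distance-to-time conversion is exact arithmetic", {
  expect_identical(distance_to_time(4800, 4.8), 60)   # an hour of walking
  expect_identical(distance_to_time(1000, 50), 1.2)   # Collector road km
  expect_identical(distance_to_time(0, 80), 0)
  expect_error(distance_to_time(100, 0), "speed")
  expect_error(distance_to_time(100, -5), "speed")
  expect_error(distance_to_time(-1, 50), "length")
})

test_that("graph building merges endpoints by tolerance only", {
  two <- geo_segments(list(cbind(c(0, 100), c(0, 0)),
                           cbind(c(100, 200), c(0, 0))),
                      mode = "road", speed_kmh = 60)
  net <- build_graph(two)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(n_components(net), 1L)

  near <- geo_segments(list(cbind(c(0, 100), c(0, 0)),
                            cbind(c(100.3, 200), c(0, 0))),
                       mode = "road", speed_kmh = 60)
  expect_equal(nrow(build_graph(near, snap_tol_m = 0.5)$nodes), 3L)

  apart <- geo_segments(list(cbind(c(0, 100), c(0, 0)),
                             cbind(c(110, 200), c(0, 0))),
                        mode = "road", speed_kmh = 60)
  expect_equal(n_components(build_graph(apart, snap_tol_m = 0.5)), 2L)
})

test_that("unresolved speeds fail naming the class", {
  seg <- geo_segments(cbind(c(0, 10), c(0, 0)), mode = "road",
                      class_label = "Cowpath")
  expect_error(build_graph(seg), "Cowpath")
})

test_that("point snapping is nearest-node with deterministic tie-break", {
  net <- build_graph(geo_segments(list(cbind(c(0, 100), c(0, 0))),
                                  mode = "road", speed_kmh = 50))
  expect_equal(snap_point(net, c(0, 0)), 1L)           # coincident
  expect_true(is.na(snap_point(net, c(50, 600), max_dist_m = 500)))
  expect_equal(snap_point(net, c(50, 10)), 1L)         # equidistant -> smaller id
})

test_that("service-area times match a line graph and respect the cutoff", {
  line <- geo_segments(list(cbind(c(0, 1000), c(0, 0)),
                            cbind(c(1000, 2000), c(0, 0))),
                       mode = "road", speed_kmh = 12)  # 5 min per km
  net <- build_graph(line)
  t30 <- one_to_many_times(net, 1L, 30)
  expect_equal(sort(unname(t30)), c(0, 5, 10))
  expect_equal(unname(t30[as.character(1L)]), 0)
  t4 <- one_to_many_times(net, 1L, 4)
  expect_equal(length(t4), 1L)
  expect_error(one_to_many_times(net, 99L, 30), "unknown source")
  # inclusive cutoff: a node exactly at the threshold stays inside
  expect_equal(length(one_to_many_times(net, 1L, 5)), 2L)
})

test_that("shortest-path times agree with exhaustive path enumeration", {
  for (s in 1:25) {
    net <- random_small_network(n_nodes = sample(4:8, 1), n_edges = 12,
                                seed = 4000 + s)
    src <- net$nodes$id[1L]
    got <- one_to_many_times(net, src, cutoff_min = 1e6)
    want <- brute_shortest_times(net, src)
    expect_equal(got[order(as.integer(names(got)))],
                 want[order(as.integer(names(want)))], tolerance = 1e-12)
  }
})

test_that("travel times are symmetric and satisfy the triangle inequality", {
  for (s in 1:8) {
    net <- random_small_network(6, 10, seed = 7000 + s)
    ids <- net$nodes$id
    d <- travel_time_matrix(net, ids, ids)
    expect_equal(d, t(d), tolerance = 1e-12)
    fin <- d; fin[!is.finite(fin)] <- 1e9
    for (u in seq_along(ids)) {
      expect_true(all(fin[u, ] <= fin[u, 1] + fin[1, ] + 1e-9))
    }
  }
})

test_that("service areas grow monotonically with the cutoff", {
  net <- random_small_network(8, 14, seed = 11)
  src <- net$nodes$id[1L]
  prev <- character(0)
  for (cut in c(1, 5, 20, 100, 1e5)) {
    nodes <- names(one_to_many_times(net, src, cut))
    expect_true(all(prev %in% nodes))
    prev <- nodes
  }
})
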