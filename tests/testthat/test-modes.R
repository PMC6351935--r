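grid_roads <- function(blocks, block_m = 100, class_label = "Collector") {
  cs <- list(); ids <- character(0)
  for (i in 0:blocks) {
    for (j in 0:(blocks - 1)) {
      cs[[length(cs) + 1L]] <- cbind(c(i, i) * block_m, c(j, j + 1) * block_m)
      ids <- c(ids, sprintf("v%d_%d", i, j))
      cs[[length(cs) + 1L]] <- cbind(c(j, j + 1) * block_m, c(i, i) * block_m)
      ids <- c(ids, sprintf("h%d_%d", i, j))
    }
  }
  geo_segments(cs, mode = "road", class_label = class_label, id = ids)
}

test_that("road edges use class-specific speeds", {
  one <- geo_segments(cbind(c(0, 1000), c(0, 0)), mode = "road",
                      class_label = "Major")
  net <- build_road_network(one)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$time_min, 1000 / (65 * 1000 / 60))  # ~0.923 min

  mixed <- geo_segments(list(cbind(c(0, 1000), c(0, 0)),
                             cbind(c(0, 1000), c(500, 500)),
                             cbind(c(0, 1000), c(1500, 1500)),
                             cbind(c(0, 1000), c(2500, 2500))),
                        mode = "road",
                        class_label = c("Collector", "Major", "Expressway",
                                        "Alley"))
  net <- build_road_network(mixed)
  got <- net$edges$time_min[match(mixed$id, net$edges$segment_id)]
  # hand-recomputed from the class speed table
  expect_equal(got, c(1000 / (50 * 1000 / 60), 1000 / (65 * 1000 / 60),
                      1000 / (80 * 1000 / 60), 1000 / (15 * 1000 / 60)))
  expect_error(build_road_network(
    geo_segments(cbind(c(0, 10), c(0, 0)), mode = "road",
                 class_label = "Goat track")), "Goat track")
})

test_that("narrative road-class names resolve through aliases", {
  sm <- speed_map()
  expect_equal(resolve_speed(sm, "primary highway", "road"), 80)
  expect_equal(resolve_speed(sm, "secondary highway", "road"), 65)
  expect_equal(resolve_speed(sm, "local road", "road"), 50)
})

test_that("a block grid has the expected node and edge counts", {
  net <- build_road_network(grid_roads(2))
  expect_equal(nrow(net$nodes), 9L)
  expect_equal(nrow(net$edges), 12L)
  expect_equal(n_components(net), 1L)
})

test_that("walking edges are timed at the constant walking speed", {
  sw <- geo_segments(cbind(c(0, 240), c(0, 0)), mode = "sidewalk")
  net <- build_walk_network(sw)
  expect_equal(net$edges$time_min, 3)  # 240 m at 4.8 km/h
})

test_that("walk network without crosswalks keeps blocks apart", {
  blocks <- geo_segments(list(cbind(c(0, 50), c(0, 0)),
                              cbind(c(60, 110), c(0, 0))),
                         mode = "sidewalk")
  expect_equal(n_components(build_walk_network(blocks)), 2L)
  bridge <- geo_segments(cbind(c(50, 60), c(0, 0)), mode = "crosswalk",
                         id = "cw")
  expect_equal(n_components(build_walk_network(blocks, bridge)), 1L)
})

# straight 2000-m bus corridor with stops at 0/1000/2000 m over a sidewalk
mm_fixture <- function(penalty = 0) {
  sw <- geo_segments(cbind(c(0, 2000), c(10, 10)), mode = "sidewalk",
                     id = "sw")
  # split so every stop has a nearby walking node
  sw <- split_segments_at_points(sw, cbind(c(1000), c(10)))
  walk <- build_walk_network(sw)
  route <- geo_segments(cbind(c(0, 2000), c(0, 0)), mode = "bus", id = "bus1")
  stops <- data.frame(id = sprintf("s%d", 1:3), x = c(0, 1000, 2000), y = 0,
                      route_id = "bus1")
  mm <- build_multimodal_network(walk, transit_layer(route, stops = stops),
                                 boarding_penalty_min = penalty)
  list(walk = walk, mm = mm)
}

test_that("bus routes split at stops and link to the sidewalk", {
  fx <- mm_fixture()
  expect_equal(sum(fx$mm$edges$mode == "bus"), 2L)
  expect_equal(sum(fx$mm$edges$mode == "link"), 3L)
  # the walking network is embedded unchanged
  expect_true(all(fx$walk$edges$segment_id %in% fx$mm$edges$segment_id))
  expect_equal(attr(fx$mm, "walk_node_ids"), fx$walk$nodes$id)
  # transit edges are incident only to stop nodes, never to walking nodes
  transit <- fx$mm$edges[fx$mm$edges$mode %in% c("bus", "train"), ]
  expect_true(all(!(c(transit$u, transit$v) %in% fx$walk$nodes$id)))
})

test_that("the bus corridor is faster than walking end to end", {
  fx <- mm_fixture()
  ends <- fx$walk$nodes$id[c(1L, nrow(fx$walk$nodes))]
  t_walk <- travel_time_matrix(fx$walk, ends[1], ends[2])[1, 1]
  t_mm <- travel_time_matrix(fx$mm, ends[1], ends[2])[1, 1]
  expect_lt(t_mm, t_walk)
  # walking 2000 m = 25 min; bus 2000 m at 40 km/h = 3 min + two 10-m links
  expect_equal(t_walk, 25)
  expect_equal(t_mm, 3 + 2 * distance_to_time(10, 4.8), tolerance = 1e-9)
})

test_that("multimodal times never exceed walking times", {
  fx <- mm_fixture()
  ids <- fx$walk$nodes$id
  dw <- travel_time_matrix(fx$walk, ids, ids)
  dm <- travel_time_matrix(fx$mm, ids, ids)
  expect_true(all(dm <= dw + 1e-9))
})

test_that("boarding penalties land on link edges only", {
  fx0 <- mm_fixture(penalty = 0)
  fx2 <- mm_fixture(penalty = 2)
  links0 <- fx0$mm$edges$time_min[fx0$mm$edges$mode == "link"]
  links2 <- fx2$mm$edges$time_min[fx2$mm$edges$mode == "link"]
  expect_equal(links2, links0 + 2)
  expect_true(all(links0 >= 0))
})

test_that("a stop off its route or far from the sidewalk is a data error", {
  sw <- geo_segments(cbind(c(0, 2000), c(10, 10)), mode = "sidewalk")
  walk <- build_walk_network(sw)
  route <- geo_segments(cbind(c(0, 2000), c(0, 0)), mode = "bus", id = "bus1")
  off_route <- data.frame(id = "bad_stop", x = 500, y = 50,
                          route_id = "bus1")
  expect_error(build_multimodal_network(
    walk, transit_layer(route, stops = off_route)), "bad_stop")
  far <- data.frame(id = "lonely", x = 500, y = 0, route_id = "bus1")
  expect_error(build_multimodal_network(
    walk, transit_layer(route, stops = far), link_max_dist_m = 5), "lonely")
})
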