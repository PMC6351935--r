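# Crosswalk generation: derive street-crossing links from fixed-radius
# buffers around road intersections. The sidewalk layers of many cities are
# digitized per block and mutually disconnected; the circle-arc procedure
# below manufactures the missing crossings.

# Angles (radians in [0, 2*pi)) at which polyline pieces cross the circle of
# radius r about center. Tangential grazes are ignored.
circle_crossing_angles <- function(segments, center, r, tol = 1e-12) {
  angles <- numeric(0)
  cx <- center[1L]; cy <- center[2L]
  for (i in seq_len(nrow(segments))) {
    m <- segments$coords[[i]]
    # bbox reject for the whole polyline
    if (min(m[, 1L]) > cx + r || max(m[, 1L]) < cx - r ||
        min(m[, 2L]) > cy + r || max(m[, 2L]) < cy - r) next
    for (k in seq_len(nrow(m) - 1L)) {
      ax <- m[k, 1L]; ay <- m[k, 2L]
      dx <- m[k + 1L, 1L] - ax; dy <- m[k + 1L, 2L] - ay
      fx <- ax - cx; fy <- ay - cy
      a <- dx * dx + dy * dy
      b <- 2 * (fx * dx + fy * dy)
      cc <- fx * fx + fy * fy - r * r
      disc <- b * b - 4 * a * cc
      if (disc <= tol || a == 0) next
      sq <- sqrt(disc)
      for (t in c((-b - sq) / (2 * a), (-b + sq) / (2 * a))) {
        if (t >= -1e-12 && t <= 1 + 1e-12) {
          px <- ax + t * dx; py <- ay + t * dy
          angles <- c(angles, atan2(py - cy, px - cx) %% (2 * pi))
        }
      }
    }
  }
  angles
}

#' Generate crosswalk arcs from road-intersection buffers
#'
#' Implements the four-step buffer procedure that turns disconnected
#' per-block sidewalks into a crossable pedestrian network: (1) buffer each
#' road intersection point by `radius_m`; (2) treat the buffer boundary as a
#' circular polyline; (3) split that circle at every point where a sidewalk
#' crosses it; (4) keep only the resulting arcs that cross a road segment —
#' those arcs are the crosswalks, spanning a road arm from the sidewalk on
#' one side to the sidewalk on the other.
#'
#' Circles crossed by fewer than two sidewalk points produce no arcs.
#'
#' @param sidewalks,roads [geo_segments()] layers in the same planar CRS.
#' @param intersections Matrix or data frame of intersection points (x, y).
#' @param radius_m Buffer radius in metres (default 18).
#' @param arc_step_deg Maximum angular spacing of emitted arc vertices.
#' @return A `geo_segments` layer with `mode = "crosswalk"` (possibly empty).
#' @export
generate_crosswalks <- function(sidewalks, intersections, roads,
                                radius_m = 18, arc_step_deg = 5) {
  check_number(radius_m, "radius_m", 0, strict = TRUE)
  if (is.null(intersections) || NROW(intersections) == 0L)
    return(empty_segments())
  pts <- as.matrix(as.data.frame(intersections)[, 1:2])
  coords_out <- list()
  ids <- character(0)
  two_pi <- 2 * pi
  for (ci in seq_len(nrow(pts))) {
    ctr <- pts[ci, ]
    sw_ang <- sort(unique(round(
      circle_crossing_angles(sidewalks, ctr, radius_m), 9)))
    if (length(sw_ang) < 2L) next
    rd_ang <- circle_crossing_angles(roads, ctr, radius_m)
    if (!length(rd_ang)) next
    k <- length(sw_ang)
    for (ai in seq_len(k)) {
      a1 <- sw_ang[ai]
      a2 <- if (ai < k) sw_ang[ai + 1L] else sw_ang[1L] + two_pi
      # retain only arcs crossed by a road
      inside <- (rd_ang > a1 + 1e-9 & rd_ang < a2 - 1e-9) |
        (rd_ang + two_pi > a1 + 1e-9 & rd_ang + two_pi < a2 - 1e-9)
      if (!any(inside)) next
      nstep <- max(2L, ceiling((a2 - a1) / (arc_step_deg * pi / 180)) + 1L)
      ang <- seq(a1, a2, length.out = nstep)
      arc <- cbind(ctr[1L] + radius_m * cos(ang),
                   ctr[2L] + radius_m * sin(ang))
      coords_out[[length(coords_out) + 1L]] <- arc
      ids <- c(ids, sprintf("cw_%d_%d", ci, ai))
    }
  }
  if (!length(coords_out)) return(empty_segments())
  geo_segments(coords_out, mode = "crosswalk", id = ids)
}
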