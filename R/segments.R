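# Polyline segment layers: the common currency of all network builders.

SEGMENT_MODES <- c("road", "sidewalk", "trail", "pathway", "crosswalk",
                   "bus", "train", "link")

polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

#' Create a layer of geographic line segments
#'
#' A `geo_segments` object is a data frame with one row per polyline feature
#' and a list-column of coordinate matrices in planar metres. It is the input
#' to all network builders.
#'
#' @param coords A list of numeric matrices, each with two columns (x, y in
#'   metres) and at least two rows, or a single such matrix.
#' @param mode Travel mode of each segment; one of `"road"`, `"sidewalk"`,
#'   `"trail"`, `"pathway"`, `"crosswalk"`, `"bus"`, `"train"`, `"link"`.
#'   Recycled.
#' @param class_label Road/route class (e.g. `"Collector"`, `"Major"`), used
#'   to resolve speeds from a [speed_map()]. Recycled; may be `NA`.
#' @param speed_kmh Optional explicit speed in km/h; when `NA` the speed is
#'   resolved later from `mode`/`class_label`. Recycled.
#' @param id Character ids; generated when `NULL`.
#' @return A data frame of class `geo_segments` with columns `id`, `mode`,
#'   `class_label`, `speed_kmh`, `length_m`, and list-column `coords`.
#' @examples
#' seg <- geo_segments(cbind(c(0, 1000), c(0, 0)), mode = "road",
#'                     class_label = "Collector")
#' seg$length_m
#' @export
geo_segments <- function(coords, mode, class_label = NA_character_,
                         speed_kmh = NA_real_, id = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  if (!is.list(coords)) stopf("`coords` must be a matrix or list of matrices")
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 2L || nrow(m) < 2L)
      stopf("each coordinate matrix needs two columns and at least two rows")
    if (any(!is.finite(m))) stopf("non-finite coordinate in segment")
    dimnames(m) <- NULL
    m
  })
  n <- length(coords)
  mode <- rep_len(as.character(mode), n)
  bad <- setdiff(unique(mode), SEGMENT_MODES)
  if (length(bad))
    stopf("unknown segment mode(s): %s", paste(bad, collapse = ", "))
  class_label <- rep_len(as.character(class_label), n)
  speed_kmh <- rep_len(as.numeric(speed_kmh), n)
  if (any(!is.na(speed_kmh) & speed_kmh <= 0))
    stopf("`speed_kmh` must be positive where given")
  if (is.null(id)) id <- sprintf("seg_%d", seq_len(n))
  id <- rep_len(as.character(id), n)
  if (anyDuplicated(id)) stopf("segment ids must be unique")
  len <- vapply(coords, polyline_length, numeric(1))
  if (any(len <= 0)) stopf("zero-length segment: %s",
                           paste(id[len <= 0], collapse = ", "))
  out <- data.frame(id = id, mode = mode, class_label = class_label,
                    speed_kmh = speed_kmh, length_m = len,
                    stringsAsFactors = FALSE)
  out$coords <- coords
  class(out) <- c("geo_segments", "data.frame")
  out
}

#' Concatenate segment layers
#'
#' @param ... `geo_segments` objects (or `NULL`s, which are dropped).
#' @return A single `geo_segments` object; ids must stay unique.
#' @export
bind_segments <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  parts <- Filter(function(p) nrow(p) > 0L, parts)
  if (!length(parts)) return(empty_segments())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  if (anyDuplicated(out$id)) stopf("duplicate segment ids after binding")
  class(out) <- c("geo_segments", "data.frame")
  out
}

empty_segments <- function() {
  out <- data.frame(id = character(), mode = character(),
                    class_label = character(), speed_kmh = numeric(),
                    length_m = numeric(), stringsAsFactors = FALSE)
  out$coords <- list()
  class(out) <- c("geo_segments", "data.frame")
  out
}

# first and last vertex of every segment; 2*n x 2 matrix ordered
# (start_1, end_1, start_2, end_2, ...)
segment_endpoints <- function(segments) {
  n <- nrow(segments)
  pts <- matrix(0, 2L * n, 2L)
  for (i in seq_len(n)) {
    m <- segments$coords[[i]]
    pts[2L * i - 1L, ] <- m[1L, ]
    pts[2L * i, ] <- m[nrow(m), ]
  }
  pts
}

# Distance from point p to segment a-b and the projection parameter t in [0,1].
point_segment_projection <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  qx <- ax + t * dx; qy <- ay + t * dy
  list(dist = sqrt((px - qx)^2 + (py - qy)^2), t = t)
}

#' Split polyline segments at points lying on them
#'
#' Each supplied point that lies on the interior of a segment (within `tol`
#' metres) splits that segment in two, with the split vertex placed exactly at
#' the supplied point so that downstream endpoint-connectivity graph building
#' joins the pieces. Points at (or within `tol` of) an existing endpoint are
#' ignored.
#'
#' @param segments A [geo_segments()] layer.
#' @param points Numeric matrix (or data frame) of x, y split locations.
#' @param tol Snap tolerance in metres.
#' @return A `geo_segments` layer; split pieces get ids `<id>.1`, `<id>.2`, ...
#' @export
split_segments_at_points <- function(segments, points, tol = 1e-6) {
  if (is.null(points) || NROW(points) == 0L || nrow(segments) == 0L)
    return(segments)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  rows <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    m <- segments$coords[[i]]
    # cumulative arc length at each vertex
    seglen <- sqrt(rowSums(diff(m)^2))
    cum <- c(0, cumsum(seglen))
    hits <- list()  # (s, x, y)
    for (p in seq_len(nrow(pts))) {
      px <- pts[p, 1L]; py <- pts[p, 2L]
      # cheap bbox reject
      if (px < min(m[, 1L]) - tol || px > max(m[, 1L]) + tol ||
          py < min(m[, 2L]) - tol || py > max(m[, 2L]) + tol) next
      for (k in seq_len(nrow(m) - 1L)) {
        pr <- point_segment_projection(px, py, m[k, 1L], m[k, 2L],
                                       m[k + 1L, 1L], m[k + 1L, 2L])
        if (pr$dist <= tol) {
          s <- cum[k] + pr$t * seglen[k]
          if (s > tol && s < cum[length(cum)] - tol)
            hits[[length(hits) + 1L]] <- c(s, px, py)
          break
        }
      }
    }
    if (!length(hits)) { rows[[i]] <- segments[i, ]; next }
    hm <- do.call(rbind, hits)
    hm <- hm[order(hm[, 1L]), , drop = FALSE]
    # drop split positions closer than tol to each other
    keep <- c(TRUE, diff(hm[, 1L]) > tol)
    hm <- hm[keep, , drop = FALSE]
    pieces <- split_polyline(m, cum, hm)
    sub <- segments[rep(i, length(pieces)), ]
    sub$id <- sprintf("%s.%d", segments$id[i], seq_along(pieces))
    sub$coords <- pieces
    sub$length_m <- vapply(pieces, polyline_length, numeric(1))
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  class(out) <- c("geo_segments", "data.frame")
  rownames(out) <- NULL
  out
}

# split one polyline (vertex cumlengths `cum`) at ordered hit rows (s, x, y)
split_polyline <- function(m, cum, hm) {
  pieces <- list()
  start_vtx <- 1L
  start_pt <- NULL  # exact coordinate opening the current piece
  for (h in seq_len(nrow(hm))) {
    s <- hm[h, 1L]
    k <- findInterval(s, cum, rightmost.closed = TRUE)  # piece index
    head <- m[start_vtx:k, , drop = FALSE]
    if (!is.null(start_pt)) head <- rbind(start_pt, head)
    piece <- rbind(head, hm[h, 2:3])
    # drop duplicate consecutive vertices
    pieces[[length(pieces) + 1L]] <- dedupe_vertices(piece)
    start_vtx <- k + 1L
    start_pt <- hm[h, 2:3]
  }
  tail <- m[start_vtx:nrow(m), , drop = FALSE]
  pieces[[length(pieces) + 1L]] <- dedupe_vertices(rbind(start_pt, tail))
  pieces
}

dedupe_vertices <- function(m, tol = 1e-9) {
  if (nrow(m) < 2L) return(m)
  keep <- c(TRUE, rowSums(abs(diff(m))) > tol)
  m[keep, , drop = FALSE]
}
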