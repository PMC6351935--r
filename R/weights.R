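# Spatial weights: symmetrized k-nearest-neighbour (default) and queen
# contiguity on supplied polygons, both row-standardized.

new_spatial_weights <- function(neighbours, ids) {
  n <- length(neighbours)
  weights <- lapply(neighbours, function(nb)
    if (length(nb)) rep(1 / length(nb), length(nb)) else numeric(0))
  structure(list(n = n, ids = ids, neighbours = neighbours,
                 weights = weights),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  card <- lengths(x$neighbours)
  cat(sprintf("<spatial_weights> n = %d, links = %d, avg neighbours = %.2f\n",
              x$n, sum(card), mean(card)))
  invisible(x)
}

#' K-nearest-neighbour spatial weights
#'
#' K nearest neighbours by Euclidean distance (ties broken by observation
#' order), symmetrized by union so the neighbour structure is symmetric, then
#' row-standardized so each non-empty row of weights sums to 1.
#'
#' @param points Matrix or data frame of coordinates (x, y).
#' @param k Number of nearest neighbours before symmetrization.
#' @param ids Optional observation ids.
#' @return An object of class `spatial_weights` with fields `n`, `ids`,
#'   `neighbours` (list of integer indices), `weights` (row-standardized).
#' @export
build_knn_weights <- function(points, k = 8, ids = NULL) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  n <- nrow(pts)
  if (n <= k) stopf("need more than k = %d points (got %d)", k, n)
  ids <- ids %||% as.character(seq_len(n))
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))  # deterministic tie-break by index
    nb[[i]] <- sort(ord[seq_len(k)])
  }
  # symmetrize by union
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!(i %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], i))
    }
  }
  new_spatial_weights(nb, ids)
}

#' Queen-contiguity spatial weights for polygons
#'
#' Two polygons are neighbours when they share at least one boundary vertex
#' (coordinates compared after rounding to `tol` metres). Suited to regular
#' lattices of census polygons; row-standardized.
#'
#' @param polygons List of polygon coordinate matrices.
#' @param ids Optional observation ids.
#' @param tol Vertex comparison tolerance in metres.
#' @return A `spatial_weights` object.
#' @export
build_queen_weights <- function(polygons, ids = NULL, tol = 1e-6) {
  n <- length(polygons)
  ids <- ids %||% as.character(seq_len(n))
  keys <- lapply(polygons, function(m) {
    m <- as.matrix(m)
    unique(paste(round(m[, 1L] / tol) * tol, round(m[, 2L] / tol) * tol))
  })
  vertex_owner <- split(rep(seq_len(n), lengths(keys)), unlist(keys))
  nb <- lapply(seq_len(n), function(i) integer(0))
  for (owners in vertex_owner) {
    owners <- unique(owners)
    if (length(owners) < 2L) next
    for (i in owners) nb[[i]] <- union(nb[[i]], setdiff(owners, i))
  }
  nb <- lapply(nb, sort)
  new_spatial_weights(nb, ids)
}

#' Dense matrix form of spatial weights
#'
#' @param W A `spatial_weights` object.
#' @return An n-by-n row-standardized matrix with zero diagonal.
#' @export
weights_matrix <- function(W) {
  m <- matrix(0, W$n, W$n, dimnames = list(W$ids, W$ids))
  for (i in seq_len(W$n)) m[i, W$neighbours[[i]]] <- W$weights[[i]]
  m
}

# flat (i, j, w) triplets, used by Moran's I
weights_triplets <- function(W) {
  card <- lengths(W$neighbours)
  list(i = rep(seq_len(W$n), card),
       j = unlist(W$neighbours, use.names = FALSE),
       w = unlist(W$weights, use.names = FALSE))
}
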