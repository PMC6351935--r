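# synthetic_city: seeded generator of a gridded city exercising every stage
# of the pipeline — roads with speed classes, deliberately disconnected
# per-block sidewalks, a core-focused bus/train system, dissemination areas
# with populations and spatially autocorrelated deprivation covariates, and
# clinics whose density decays away from the centre.

PAMPALON_VARS <- c(
  "Proportion of the individuals separated, divorced, or widowed",
  "Proportion of the persons living alone",
  "Proportion of single-parent families",
  "Proportion of persons without a high school diploma",
  "Employment-population ratio",
  "Average income")

#' Synthetic-city configuration
#'
#' @param blocks_per_side Number of city blocks per side (>= 4; default 20,
#'   i.e. 400 dissemination areas).
#' @param block_m Block edge length in metres (default 200).
#' @param major_every Every `major_every`-th grid line is a Major road, the
#'   rest Collector (default 5).
#' @param bus_corridor_every Bus corridors run along every
#'   `bus_corridor_every`-th interior horizontal Major row (default 5).
#' @param bus_span Fraction of the city width served by bus corridors,
#'   centred (default the central half, `c(0.25, 0.75)`): transit coverage
#'   thins toward the periphery, as in most real systems.
#' @param stop_spacing_m Bus-stop spacing along corridors (default 400).
#' @param station_spacing_m Train-station spacing (default 800).
#' @param clinic_count Number of clinics (default 30).
#' @param clinic_center_bias Exponential decay rate of clinic density with
#'   distance from the centre; 0 gives uniform placement (default 2).
#' @param providers_lambda Providers per clinic are `1 + Poisson(lambda)`
#'   (default 2).
#' @param sidewalk_inset_m Sidewalk offset from the block edge (default 6;
#'   keeps block rings within the 18-m crossing buffer of each intersection).
#' @param da_jitter_m Uniform jitter of the population-weighted centroid
#'   around the block centre (default 20).
#' @param seed Integer seed; required, all layers are reproducible from it.
#' @param sar_rho Spatial autocorrelation of the covariate fields (default
#'   0.5).
#' @param collinear_pair Generate the no-high-school-diploma variable nearly
#'   collinear (|r| >= 0.9) with the single-parent variable, to exercise the
#'   correlation filter (default `TRUE`).
#' @param add_trails Add diagonal park trails across some blocks (default
#'   `FALSE`).
#' @return An object of class `city_config`.
#' @export
city_config <- function(blocks_per_side = 20, block_m = 200, major_every = 5,
                        bus_corridor_every = 5, bus_span = c(0.25, 0.75),
                        stop_spacing_m = 400, station_spacing_m = 800,
                        clinic_count = 30, clinic_center_bias = 2,
                        providers_lambda = 2, sidewalk_inset_m = 6,
                        da_jitter_m = 20, seed = 42, sar_rho = 0.5,
                        collinear_pair = TRUE, add_trails = FALSE) {
  if (blocks_per_side < 4) stopf("`blocks_per_side` must be >= 4")
  check_number(block_m, "block_m", 0, strict = TRUE)
  if (is.null(seed) || !is.finite(seed)) stopf("`seed` is required")
  if (abs(sar_rho) >= 1) stopf("`sar_rho` must lie in (-1, 1)")
  check_number(clinic_center_bias, "clinic_center_bias", 0)
  if (sidewalk_inset_m <= 0 || sidewalk_inset_m >= block_m / 2)
    stopf("`sidewalk_inset_m` must lie in (0, block_m/2)")
  vals <- mget(names(formals(city_config)))
  # store numbers as doubles so configs survive a JSON round trip unchanged
  vals <- lapply(vals, function(v) if (is.numeric(v)) as.numeric(v) else v)
  structure(vals, class = "city_config")
}

#' Generate a synthetic city
#'
#' Deterministic given the config (which includes the seed): the same config
#' produces byte-identical layers.
#'
#' @param config A [city_config()].
#' @return An object of class `city_bundle`: segment layers `roads`,
#'   `sidewalks`, `trails`, `bus_routes`, `train_lines`; point tables
#'   `intersections`, `bus_stops`, `stations`, `clinics`; `das`
#'   (dissemination areas with centroid, population, area, and polygon) and
#'   `covariates` (six deprivation variables); plus the `config`.
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  with_seed(config$seed, generate_city_impl(config))
}

generate_city_impl <- function(cfg) {
  B <- cfg$blocks_per_side
  b <- cfg$block_m
  L <- B * b
  road_class <- function(i) if (i %% cfg$major_every == 0) "Major" else "Collector"
  # roads: grid lines split per block (endpoint connectivity at intersections)
  rc <- list(); rid <- character(0); rcl <- character(0)
  for (i in 0:B) {         # vertical lines x = i*b
    for (j in 0:(B - 1)) {
      rc[[length(rc) + 1L]] <- cbind(c(i * b, i * b), c(j * b, (j + 1) * b))
      rid <- c(rid, sprintf("rv_%d_%d", i, j)); rcl <- c(rcl, road_class(i))
    }
  }
  for (j in 0:B) {         # horizontal lines y = j*b
    for (i in 0:(B - 1)) {
      rc[[length(rc) + 1L]] <- cbind(c(i * b, (i + 1) * b), c(j * b, j * b))
      rid <- c(rid, sprintf("rh_%d_%d", j, i)); rcl <- c(rcl, road_class(j))
    }
  }
  roads <- geo_segments(rc, mode = "road", class_label = rcl, id = rid)
  intersections <- expand.grid(x = (0:B) * b, y = (0:B) * b,
                               KEEP.OUT.ATTRS = FALSE)
  # sidewalks: one inset ring per block, connected within the block but
  # disconnected from every other block
  s <- cfg$sidewalk_inset_m
  sc <- list(); sid <- character(0)
  for (i in 0:(B - 1)) {
    for (j in 0:(B - 1)) {
      x0 <- i * b + s; x1 <- (i + 1) * b - s
      y0 <- j * b + s; y1 <- (j + 1) * b - s
      ring <- list(cbind(c(x0, x1), c(y0, y0)), cbind(c(x1, x1), c(y0, y1)),
                   cbind(c(x1, x0), c(y1, y1)), cbind(c(x0, x0), c(y1, y0)))
      sc <- c(sc, ring)
      sid <- c(sid, sprintf("sw_%d_%d_%d", i, j, 1:4))
    }
  }
  sidewalks <- geo_segments(sc, mode = "sidewalk", id = sid)
  trails <- empty_segments()
  if (cfg$add_trails) {
    tc <- list(); tid <- character(0)
    for (i in 0:(B - 1)) {
      for (j in 0:(B - 1)) {
        if ((i + j) %% 7 != 0) next
        tc[[length(tc) + 1L]] <- cbind(c(i * b + s, (i + 1) * b - s),
                                       c(j * b + s, (j + 1) * b - s))
        tid <- c(tid, sprintf("tr_%d_%d", i, j))
      }
    }
    if (length(tc)) trails <- geo_segments(tc, mode = "trail", id = tid)
  }
  # bus corridors: interior Major rows, central span only
  rows <- seq(0, B, by = cfg$bus_corridor_every)
  rows <- rows[rows > 0 & rows < B]
  if (!length(rows)) rows <- floor(B / 2)
  x0 <- round(B * cfg$bus_span[1]) * b
  x1 <- round(B * cfg$bus_span[2]) * b
  bc <- list(); bid <- character(0)
  stops <- list()
  for (r in rows) {
    y <- r * b
    route_id <- sprintf("bus_%d", r)
    bc[[length(bc) + 1L]] <- cbind(c(x0, x1), c(y, y))
    bid <- c(bid, route_id)
    sx <- seq(x0, x1, by = cfg$stop_spacing_m)
    if (sx[length(sx)] < x1) sx <- c(sx, x1)
    stops[[length(stops) + 1L]] <- data.frame(
      id = sprintf("bs_%d_%d", r, seq_along(sx)), x = sx, y = y,
      route_id = route_id, stringsAsFactors = FALSE)
  }
  bus_routes <- geo_segments(bc, mode = "bus", id = bid)
  bus_stops <- do.call(rbind, stops)
  # one central train line, full span
  tx <- floor(B / 2) * b
  train_lines <- geo_segments(cbind(c(tx, tx), c(0, L)), mode = "train",
                              id = "train_1")
  sy <- seq(0, L, by = cfg$station_spacing_m)
  if (sy[length(sy)] < L) sy <- c(sy, L)
  stations <- data.frame(id = sprintf("st_%d", seq_along(sy)), x = tx, y = sy,
                         route_id = "train_1", stringsAsFactors = FALSE)
  # dissemination areas: one per block
  n_da <- B * B
  idx <- 0L
  da_rows <- vector("list", n_da)
  polys <- vector("list", n_da)
  for (j in 0:(B - 1)) {
    for (i in 0:(B - 1)) {
      idx <- idx + 1L
      cx <- (i + 0.5) * b + stats::runif(1, -cfg$da_jitter_m, cfg$da_jitter_m)
      cy <- (j + 0.5) * b + stats::runif(1, -cfg$da_jitter_m, cfg$da_jitter_m)
      da_rows[[idx]] <- data.frame(
        id = sprintf("da_%04d", idx), x = cx, y = cy,
        population = sample(400:700, 1L),
        area_km2 = (b / 1000)^2, stringsAsFactors = FALSE)
      polys[[idx]] <- cbind(c(i, i + 1, i + 1, i, i) * b,
                            c(j, j, j + 1, j + 1, j) * b)
    }
  }
  das <- do.call(rbind, da_rows)
  das$polygon <- polys
  # clinics: density decays from the centre
  ctr <- c(L / 2, L / 2)
  bx <- (rep(0:(B - 1), each = B) + 0.5) * b
  by <- (rep(0:(B - 1), times = B) + 0.5) * b
  dctr <- sqrt((bx - ctr[1])^2 + (by - ctr[2])^2)
  prob <- exp(-cfg$clinic_center_bias * dctr / max(dctr))
  blocks <- sample.int(B * B, cfg$clinic_count, replace = TRUE,
                       prob = prob / sum(prob))
  clinics <- data.frame(
    id = sprintf("cl_%02d", seq_len(cfg$clinic_count)),
    x = bx[blocks] + stats::runif(cfg$clinic_count, -b / 4, b / 4),
    y = by[blocks] + stats::runif(cfg$clinic_count, -b / 4, b / 4),
    providers = 1L + stats::rpois(cfg$clinic_count, cfg$providers_lambda),
    stringsAsFactors = FALSE)
  W <- build_knn_weights(das[, c("x", "y")], k = min(8L, n_da - 1L),
                         ids = das$id)
  covariates <- generate_covariates(das, W, cfg)
  structure(list(config = cfg, roads = roads, sidewalks = sidewalks,
                 trails = trails, intersections = intersections,
                 bus_routes = bus_routes, bus_stops = bus_stops,
                 train_lines = train_lines, stations = stations,
                 das = das, clinics = clinics, covariates = covariates),
            class = "city_bundle")
}

#' @export
print.city_bundle <- function(x, ...) {
  cat(sprintf(
    "<city_bundle> %d DAs, %d clinics, %d road / %d sidewalk segments, %d bus stops, %d stations\n",
    nrow(x$das), nrow(x$clinics), nrow(x$roads), nrow(x$sidewalks),
    nrow(x$bus_stops), nrow(x$stations)))
  invisible(x)
}

#' Generate deprivation covariates for dissemination areas
#'
#' Six area-level deprivation variables (the proportions and income used in
#' small-area material/social deprivation indices), each built from a
#' spatially autoregressive latent field plus a centre-distance trend so the
#' regression stages have genuine spatial signal. Proportions are mapped
#' through the logistic function, so they always lie in `[0, 1]`; income is
#' log-normal and positive. When `config$collinear_pair` is set, the
#' no-high-school-diploma variable is generated nearly collinear with the
#' single-parent variable to exercise the correlation filter.
#'
#' @param das Data frame of dissemination areas with centroid columns
#'   `x`, `y` and `id`.
#' @param W `spatial_weights` built on the DA centroids.
#' @param config A [city_config()] (`sar_rho`, `collinear_pair`,
#'   `blocks_per_side`, `block_m` are used).
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside [generate_city()]).
#' @return Data frame with `id` and the six covariates.
#' @export
generate_covariates <- function(das, W, config, seed = NULL) {
  with_seed(seed, {
    n <- nrow(das)
    L <- config$blocks_per_side * config$block_m
    cdist <- sqrt((das$x - L / 2)^2 + (das$y - L / 2)^2)
    cdist <- cdist / max(cdist)
    field <- function() simulate_sar(W, config$sar_rho, numeric(0), 0.5,
                                     matrix(0, n, 0))
    l_sep <- -1.8 + 0.8 * cdist + field()
    l_alone <- -1.0 - 1.5 * cdist + field()
    l_spar <- -1.9 - 0.4 * cdist + field()
    l_nohs <- if (isTRUE(config$collinear_pair)) {
      l_spar + 0.1 + stats::rnorm(n, 0, 0.1)
    } else {
      -1.4 + 0.5 * cdist + field()
    }
    l_emp <- 1.1 + 0.3 * cdist + field()
    income <- round(35000 * exp(-0.35 * cdist + 0.25 * field()))
    out <- data.frame(id = das$id, stringsAsFactors = FALSE)
    out[[PAMPALON_VARS[1]]] <- stats::plogis(l_sep)
    out[[PAMPALON_VARS[2]]] <- stats::plogis(l_alone)
    out[[PAMPALON_VARS[3]]] <- stats::plogis(l_spar)
    out[[PAMPALON_VARS[4]]] <- stats::plogis(l_nohs)
    out[[PAMPALON_VARS[5]]] <- stats::plogis(l_emp)
    out[[PAMPALON_VARS[6]]] <- income
    out
  })
}
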