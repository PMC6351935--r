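# e2sfca: Enhanced Two-Step Floating Catchment Area accessibility,
# Spatial Access Ratio normalization, quantile classification, and
# shortage-area summaries.

#' Three-zone distance-decay scheme
#'
#' The 30-minute catchment is divided into travel-time subzones with a
#' stepwise decay weight per zone. The defaults are the sharp urban decay
#' weights 1.00 / 0.42 / 0.09 over 0-10 / 10-20 / 20-30 minutes, appropriate
#' where many facilities compete and people rarely travel to distant ones.
#'
#' @param breaks Strictly increasing positive zone upper bounds in minutes.
#'   The last break is the catchment radius.
#' @param weights Strictly decreasing weights in (0, 1], one per zone.
#' @return An object of class `decay_scheme`.
#' @examples
#' sc <- decay_scheme()
#' zone_weight(c(5, 15, 25, 35), sc)
#' @export
decay_scheme <- function(breaks = c(10, 20, 30),
                         weights = c(1.00, 0.42, 0.09)) {
  if (length(breaks) != length(weights))
    stopf("`breaks` and `weights` must have the same length")
  if (any(breaks <= 0) || any(diff(breaks) <= 0))
    stopf("`breaks` must be positive and strictly increasing")
  if (any(weights <= 0) || any(weights > 1) || any(diff(weights) >= 0))
    stopf("`weights` must be strictly decreasing within (0, 1]")
  structure(list(breaks = breaks, weights = weights), class = "decay_scheme")
}

#' Distance-decay weight of a travel time
#'
#' Zone intervals are closed on the right: a time of exactly 10 minutes falls
#' in the first zone, and a time equal to the last break is still inside the
#' catchment. Times beyond the catchment (including `Inf` for unreachable
#' pairs) get weight 0.
#'
#' @param t Travel time(s) in minutes; must be non-negative (`Inf` allowed).
#' @param scheme A [decay_scheme()].
#' @return Numeric weight(s).
#' @export
zone_weight <- function(t, scheme = decay_scheme()) {
  if (any(is.na(t)) || any(t < 0)) stopf("travel times must be non-negative")
  zone <- findInterval(t, scheme$breaks, left.open = TRUE) + 1L
  c(scheme$weights, rep(0, length(scheme$breaks)))[
    pmin(zone, length(scheme$breaks) + 1L)]
}

#' Step 1: provider-to-population ratio of one facility
#'
#' The facility's supply divided by the decay-weighted population inside its
#' catchment: `R_j = S_j / sum_k P_k W(t_kj)` over population locations `k`
#' with `t_kj` within the last zone break. A facility with no population in
#' its catchment gets `r_j = 0` and is flagged `catchment_empty`.
#'
#' @param providers Number of providers at the facility (`S_j`, `>= 0`).
#' @param times Named numeric vector of travel times in minutes, names are
#'   population location ids; locations absent from `times` are unreachable.
#' @param populations Data frame with columns `id` and `population`.
#' @param scheme A [decay_scheme()].
#' @return List with `r_j` (providers per person) and `catchment_empty`.
#' @export
step1_provider_ratio <- function(providers, times, populations,
                                 scheme = decay_scheme()) {
  check_number(providers, "providers", 0)
  if (any(populations$population < 0)) stopf("negative population")
  pop <- populations$population[match(names(times), populations$id)]
  if (any(is.na(pop)))
    stopf("travel times refer to unknown population ids: %s",
          paste(names(times)[is.na(pop)], collapse = ", "))
  denom <- sum(pop * zone_weight(times, scheme))
  if (denom <= 0) return(list(r_j = 0, catchment_empty = TRUE))
  list(r_j = providers / denom, catchment_empty = FALSE)
}

#' Step 2: accessibility index of one population location
#'
#' The decay-weighted sum of the provider-to-population ratios of every
#' facility within the catchment: `A_i = sum_j R_j W(t_ij)`.
#'
#' @param ratios Named numeric vector of `R_j` values, names are facility ids.
#' @param times Named numeric vector of minutes from the location to
#'   facilities; facilities absent from `times` are unreachable.
#' @param scheme A [decay_scheme()].
#' @return The accessibility index (providers per person).
#' @export
step2_accessibility <- function(ratios, times, scheme = decay_scheme()) {
  if (!length(times)) return(0)
  r <- ratios[names(times)]
  if (any(is.na(r)))
    stopf("travel times refer to unknown facility ids: %s",
          paste(names(times)[is.na(r)], collapse = ", "))
  sum(r * zone_weight(times, scheme))
}

#' Full E2SFCA computation from a travel-time matrix
#'
#' Runs Step 1 for every facility and Step 2 for every population location
#' on one facility-by-location travel-time matrix (so both steps use the
#' same, symmetric travel times).
#'
#' @param time_matrix Matrix of minutes, rows = facilities, columns =
#'   population locations; `Inf` marks unreachable pairs. Dimnames carry the
#'   ids.
#' @param providers Numeric vector of facility supply `S_j` (row order).
#' @param population Numeric vector of population `P_k` (column order).
#' @param scheme A [decay_scheme()].
#' @return List with data frames `ratios` (`facility_id`, `r_j`,
#'   `catchment_empty`) and `access` (`location_id`, `a_index`).
#' @export
e2sfca <- function(time_matrix, providers, population,
                   scheme = decay_scheme()) {
  stopifnot(is.matrix(time_matrix),
            length(providers) == nrow(time_matrix),
            length(population) == ncol(time_matrix))
  if (any(population < 0)) stopf("negative population")
  if (any(providers < 0)) stopf("negative provider count")
  w <- matrix(zone_weight(as.vector(time_matrix), scheme),
              nrow = nrow(time_matrix))
  denom <- as.vector(w %*% population)
  r_j <- ifelse(denom > 0, providers / denom, 0)
  a <- as.vector(crossprod(w, r_j))
  fid <- rownames(time_matrix) %||% as.character(seq_along(providers))
  lid <- colnames(time_matrix) %||% as.character(seq_along(population))
  list(ratios = data.frame(facility_id = fid, r_j = r_j,
                           catchment_empty = denom <= 0,
                           stringsAsFactors = FALSE),
       access = data.frame(location_id = lid, a_index = a,
                           stringsAsFactors = FALSE))
}

#' Spatial Access Ratio normalization
#'
#' Divides each accessibility index by the unweighted mean index over all
#' population locations (zeros included), yielding a dimensionless ratio
#' that is robust to the choice of distance-impedance parameters.
#'
#' @param a_indices Numeric vector of accessibility indices over all
#'   population locations; at least one must be positive.
#' @return Numeric vector of SPAR values with mean 1.
#' @export
spar <- function(a_indices) {
  if (any(a_indices < 0)) stopf("accessibility indices must be non-negative")
  m <- mean(a_indices)
  if (m <= 0)
    stopf("all accessibility indices are zero; SPAR is undefined (no facility reachable from any location)")
  a_indices / m
}

#' Quantile classification of SPAR values, isolating zeros
#'
#' Zero values (no reachable facility) get their own `"no access"` class;
#' positive values are split into `n_classes` equal-count groups by rank,
#' with ties resolved in stable input order. Purely cartographic.
#'
#' @param spars Numeric vector of SPAR values.
#' @param n_classes Number of quantile classes for the positive values.
#' @return Character vector of labels: `"no access"` or `"Q1"` (lowest)
#'   through `"Q<n_classes>"` (highest).
#' @export
classify_quantiles <- function(spars, n_classes = 5) {
  out <- character(length(spars))
  pos <- spars > 0
  out[!pos] <- "no access"
  if (any(pos)) {
    r <- rank(spars[pos], ties.method = "first")
    cls <- ceiling(r * n_classes / sum(pos))
    out[pos] <- sprintf("Q%d", pmax(1L, cls))
  }
  out
}

#' Shortage-area summary
#'
#' Sums area and population over the shortage areas (locations with SPAR 0,
#' i.e. no facility reachable within the catchment) and expresses the
#' shortage population as a percentage of the total population.
#'
#' @param records Data frame with columns `location_id` and `spar`.
#' @param populations Data frame with columns `id`, `population`, `area_km2`;
#'   ids must match `records$location_id` one-to-one.
#' @return Data frame row: `area_km2`, `population`, `percent_of_total`
#'   (rounded to one decimal, as conventionally reported), and
#'   `percent_exact` (unrounded).
#' @export
shortage_summary <- function(records, populations) {
  if (!setequal(records$location_id, populations$id) ||
      nrow(records) != nrow(populations))
    stopf("records and populations must cover the same location ids")
  pop <- populations[match(records$location_id, populations$id), ]
  short <- records$spar == 0
  total <- sum(pop$population)
  spop <- sum(pop$population[short])
  pct <- if (total > 0) 100 * spop / total else 0
  data.frame(area_km2 = sum(pop$area_km2[short]), population = spop,
             percent_of_total = round(pct, 1), percent_exact = pct)
}
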