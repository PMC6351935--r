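# cli_reporting: end-to-end orchestration of the three-mode accessibility
# comparison — network build, travel-time matrices, E2SFCA, SPAR, quantile
# classes, shortage summaries, and the spatial statistics — plus report
# writing with a checksummed manifest.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full multimodal accessibility pipeline
#'
#' For each requested mode: builds the mode's network, snaps clinics and DA
#' centroids to it, computes the facility-by-location travel-time matrix
#' (one matrix per mode, shared by both E2SFCA steps), runs E2SFCA, SPAR,
#' quantile classification, and the shortage summary; then computes the
#' spatial statistics (correlation filter, Moran's I on SPAR and on OLS
#' residuals, OLS, spatial-lag regression). Optionally writes all reports to
#' a directory with a checksummed manifest.
#'
#' @param bundle A `city_bundle` (from [generate_city()] or [read_layers()])
#'   or a directory path of layers.
#' @param modes Subset of `c("drive", "walk", "multimodal")`.
#' @param scheme A [decay_scheme()]; its last break is the catchment cutoff.
#' @param speeds A [speed_map()].
#' @param weights_type `"knn"` or `"queen"` spatial weights for the
#'   statistics stage.
#' @param k Neighbours for knn weights.
#' @param n_perm Moran permutations.
#' @param cor_cutoff Correlation-filter threshold.
#' @param snap_max_m Maximum clinic/DA snap distance to a network node.
#' @param link_max_dist_m Maximum stop-to-sidewalk link distance.
#' @param boarding_penalty_min Transit boarding penalty in minutes.
#' @param seed Seed for the permutation draws.
#' @param out_dir If non-`NULL`, reports are written here.
#' @param verbose Log stage progress to stderr.
#' @return An object of class `spar_run`: `access` (one data frame per
#'   mode: location, a_index, spar, quantile_class, population, area_km2),
#'   `shortage` (one row per mode), `ratios`, `stats` (per mode: retained
#'   variables, Moran results, OLS and spatial-lag fits), `networks`
#'   summaries, and the configuration used.
#' @export
run_pipeline <- function(bundle, modes = c("drive", "walk", "multimodal"),
                         scheme = decay_scheme(), speeds = speed_map(),
                         weights_type = c("knn", "queen"), k = 8,
                         n_perm = 999, cor_cutoff = 0.70,
                         snap_max_m = 500, link_max_dist_m = 100,
                         boarding_penalty_min = 0, seed = 1,
                         out_dir = NULL, verbose = FALSE) {
  if (is.character(bundle)) bundle <- read_layers(bundle)
  stopifnot(inherits(bundle, "city_bundle"))
  modes <- match.arg(modes, c("drive", "walk", "multimodal"),
                     several.ok = TRUE)
  weights_type <- match.arg(weights_type)
  say <- function(...) if (verbose) message(sprintf(...))
  cutoff <- max(scheme$breaks)
  if (nrow(bundle$clinics) == 0L)
    stopf("pipeline stage 'spar' failed: no clinics supplied, all accessibility indices would be zero")
  t_start <- proc.time()[["elapsed"]]

  networks <- list()
  if (any(c("walk", "multimodal") %in% modes)) {
    crosswalks <- stage("crosswalks", generate_crosswalks(
      bundle$sidewalks, bundle$intersections, bundle$roads))
    say("crosswalks: %d arcs", nrow(crosswalks))
    walk_net <- stage("walk_network", build_walk_network(
      bundle$sidewalks, crosswalks,
      trails = if (nrow(bundle$trails)) bundle$trails else NULL,
      speeds = speeds))
    networks$walk <- walk_net
  }
  if ("drive" %in% modes) {
    networks$drive <- stage("road_network",
                            build_road_network(bundle$roads, speeds))
  }
  if ("multimodal" %in% modes) {
    transit <- transit_layer(
      bind_segments(bundle$bus_routes, bundle$train_lines),
      stops = bundle$bus_stops, stations = bundle$stations)
    networks$multimodal <- stage("multimodal_network",
      build_multimodal_network(networks$walk, transit, speeds,
                               boarding_penalty_min = boarding_penalty_min,
                               link_max_dist_m = link_max_dist_m))
  }

  das <- bundle$das
  clinics <- bundle$clinics
  access <- list(); ratios <- list(); shortage <- list()
  for (mode in modes) {
    net <- networks[[mode]]
    walk_ids <- attr(net, "walk_node_ids")  # restrict snapping for multimodal
    snap_one <- function(pt, id, kind) {
      nid <- snap_point(net, pt, max_dist_m = snap_max_m,
                        node_ids = walk_ids)
      if (is.na(nid))
        stopf("pipeline stage 'snap/%s' failed: %s '%s' has no network node within %g m",
              mode, kind, id, snap_max_m)
      nid
    }
    fac_nodes <- vapply(seq_len(nrow(clinics)), function(i)
      snap_one(c(clinics$x[i], clinics$y[i]), clinics$id[i], "clinic"),
      integer(1))
    da_nodes <- vapply(seq_len(nrow(das)), function(i)
      snap_one(c(das$x[i], das$y[i]), das$id[i], "DA"), integer(1))
    tmat <- stage(paste0("times/", mode),
                  travel_time_matrix(net, fac_nodes, da_nodes))
    dimnames(tmat) <- list(clinics$id, das$id)
    res <- stage(paste0("e2sfca/", mode),
                 e2sfca(tmat, clinics$providers, das$population, scheme))
    sp <- stage(paste0("spar/", mode), spar(res$access$a_index))
    acc <- data.frame(location_id = das$id, mode = mode,
                      a_index = res$access$a_index, spar = sp,
                      quantile_class = classify_quantiles(sp),
                      population = das$population, area_km2 = das$area_km2,
                      stringsAsFactors = FALSE)
    access[[mode]] <- acc
    ratios[[mode]] <- cbind(res$ratios, mode = mode)
    sh <- shortage_summary(acc, das)
    shortage[[mode]] <- cbind(mode = mode, sh)
    say("%s: mean time %.1f min, shortage %d people", mode,
        mean(tmat[is.finite(tmat)]), sh$population)
  }
  shortage <- do.call(rbind, shortage)

  W <- stage("weights", switch(weights_type,
    knn = build_knn_weights(das[, c("x", "y")], k = k, ids = das$id),
    queen = build_queen_weights(das$polygon, ids = das$id)))
  X_all <- bundle$covariates[match(das$id, bundle$covariates$id), -1,
                             drop = FALSE]
  retained <- stage("correlation_filter",
                    correlation_filter(X_all, cutoff = cor_cutoff))
  X <- as.matrix(X_all[, retained, drop = FALSE])
  stats_out <- list()
  for (mi in seq_along(modes)) {
    mode <- modes[mi]
    sp <- access[[mode]]$spar
    mseed <- seed + mi
    if (stats::var(sp) == 0) {
      # uniform access (e.g. every pair inside the first decay zone):
      # autocorrelation and regression on a constant response are undefined
      stats_out[[mode]] <- list(degenerate = TRUE,
                                reason = "SPAR constant across locations")
      say("%s: SPAR constant; statistics stage skipped", mode)
      next
    }
    moran_spar <- stage(paste0("moran/", mode),
                        morans_i(sp, W, n_perm = n_perm, seed = mseed))
    ols <- stage(paste0("ols/", mode), fit_ols(sp, X))
    moran_resid <- stage(paste0("moran_resid/", mode),
                         morans_i(ols$residuals, W, n_perm = n_perm,
                                  seed = mseed + 1000L))
    lag <- stage(paste0("spatial_lag/", mode), fit_spatial_lag(sp, X, W))
    stats_out[[mode]] <- list(moran_spar = moran_spar,
                              moran_resid = moran_resid,
                              ols = ols, lag = lag)
  }

  run <- structure(list(
    modes = modes, access = access, ratios = ratios, shortage = shortage,
    stats = stats_out, retained = retained, networks = networks,
    settings = list(scheme = scheme, cutoff_min = cutoff,
                    weights_type = weights_type, k = k, n_perm = n_perm,
                    cor_cutoff = cor_cutoff, snap_max_m = snap_max_m,
                    boarding_penalty_min = boarding_penalty_min,
                    seed = seed),
    das = das,
    elapsed_s = proc.time()[["elapsed"]] - t_start),
    class = "spar_run")
  if (!is.null(out_dir)) write_reports(run, out_dir, bundle = bundle)
  run
}

#' @export
print.spar_run <- function(x, ...) {
  cat("<spar_run> modes:", paste(x$modes, collapse = ", "), "\n")
  print(x$shortage, row.names = FALSE)
  invisible(x)
}

fmt6 <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  }
  df
}

regression_table <- function(lag) {
  data.frame(term = names(lag$coefficients),
             Estimate = unname(lag$coefficients),
             `Std. Error` = unname(lag$se),
             `z-Value` = unname(lag$z),
             `p-Value` = unname(lag$p_value),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write pipeline reports
#'
#' Writes per-mode access tables, the shortage summary, Moran and regression
#' reports (all CSV, 6 significant digits), a full-precision JSON report, an
#' access-surface GeoJSON when the bundle is supplied, and `manifest.json`
#' listing every output file with its MD5 checksum, the seed, and the
#' package version. Two runs with the same inputs produce byte-identical
#' files.
#'
#' @param run A `spar_run`.
#' @param dir Output directory.
#' @param bundle Optional `city_bundle` for the access-surface GeoJSON.
#' @return Invisibly, the manifest as a list.
#' @export
write_reports <- function(run, dir, bundle = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(fmt6(df), path, row.names = FALSE)
    files <<- c(files, name)
  }
  fitted_modes <- Filter(function(m) is.null(run$stats[[m]]$degenerate),
                         run$modes)
  for (mode in run$modes) {
    put(run$access[[mode]], sprintf("access_%s.csv", mode))
    if (mode %in% fitted_modes)
      put(regression_table(run$stats[[mode]]$lag),
          sprintf("regression_%s.csv", mode))
  }
  put(run$shortage, "shortage_summary.csv")
  if (length(fitted_modes)) {
    moran_tab <- do.call(rbind, lapply(fitted_modes, function(m) {
      st <- run$stats[[m]]
      data.frame(mode = m,
                 morans_i_spar = st$moran_spar$i_value,
                 p_spar = st$moran_spar$p_perm,
                 morans_i_ols_residuals = st$moran_resid$i_value,
                 p_residuals = st$moran_resid$p_perm)
    }))
    put(moran_tab, "moran.csv")
    footer <- do.call(rbind, lapply(fitted_modes, function(m) {
      lag <- run$stats[[m]]$lag
      data.frame(mode = m, rho = lag$rho, lr_stat = lag$lr_stat,
                 lr_p = lag$lr_p, aic = lag$aic, aic_ols = lag$ols$aic)
    }))
    put(footer, "spatial_lag_summary.csv")
  }
  # full-precision machine-readable report
  report <- list(
    shortage = run$shortage,
    retained_variables = run$retained,
    settings = run$settings[setdiff(names(run$settings), "scheme")],
    decay = unclass(run$settings$scheme),
    spatial_lag = lapply(run$stats, function(st) {
      if (isTRUE(st$degenerate)) return(list(degenerate = TRUE,
                                             reason = st$reason))
      list(rho = st$lag$rho, coefficients = as.list(st$lag$coefficients),
           lr_stat = st$lag$lr_stat, lr_p = st$lag$lr_p, aic = st$lag$aic)
    }))
  report_path <- file.path(dir, "report.json")
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"), report_path)
  files <- c(files, "report.json")
  if (!is.null(bundle)) {
    for (mode in run$modes) {
      name <- sprintf("access_surface_%s.geojson", mode)
      write_das_geojson(bundle$das, file.path(dir, name),
                        extra = run$access[[mode]][
                          , c("location_id", "a_index", "spar",
                              "quantile_class")])
      files <- c(files, name)
    }
  }
  sums <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    package = "sparaccess",
    version = as.character(utils::packageVersion("sparaccess")),
    seed = run$settings$seed,
    modes = run$modes,
    files = data.frame(file = files, md5 = unname(sums),
                       stringsAsFactors = FALSE))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}
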