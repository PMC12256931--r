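#' Pipeline run configuration
#'
#' All published analysis settings in one place; defaults equal the study
#' settings (150 m cells, 10 km clip buffer, 150 m node-merge radius, top
#' 5% of paths, 1200 m corridors).
#'
#' @param landscape a [landscape_config()] for the synthetic inputs.
#' @param n_snag_sites number of hair-snag sites to simulate.
#' @param cell_size_m analysis resolution (m).
#' @param clip_buffer_m edge-effect buffer around the study boundary (m).
#' @param merge_radius_m focal-node merge radius (m).
#' @param top_fraction fraction of least-cost paths kept as corridors.
#' @param corridor_width_m total corridor width (m).
#' @param detection a [detection_model()] for the validation stage; by
#'   default the home-range scale is set to 1/8 of the landscape extent so
#'   that simulated home ranges cover a few neighbouring sites, as in the
#'   full-scale study system.
#' @param seed master seed for every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(landscape = landscape_config(),
                       n_snag_sites = 20L,
                       cell_size_m = 150, clip_buffer_m = 10000,
                       merge_radius_m = 150, top_fraction = 0.05,
                       corridor_width_m = 1200,
                       detection = NULL, seed = 1L) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("`top_fraction` must be in (0, 1]")
  if (is.null(detection))
    detection <- detection_model(
      home_range_sigma_m = min(landscape$extent_m) / 8)
  structure(list(
    landscape = landscape, n_snag_sites = as.integer(n_snag_sites),
    cell_size_m = cell_size_m, clip_buffer_m = clip_buffer_m,
    merge_radius_m = merge_radius_m, top_fraction = top_fraction,
    corridor_width_m = corridor_width_m, detection = detection,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may set any [run_config()] field; `landscape:` is a nested
#' section of [landscape_config()] fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ls_args <- raw$landscape %||% list()
  det_args <- raw$detection
  raw$landscape <- NULL; raw$detection <- NULL
  extra <- list(landscape = do.call(landscape_config, ls_args))
  if (!is.null(det_args)) {
    if (!is.null(det_args$n_individuals))
      det_args$n_individuals <- unlist(det_args$n_individuals)
    extra$detection <- do.call(detection_model, det_args)
  }
  do.call(run_config, c(raw, extra))
}

#' Run the full connectivity pipeline on a synthetic landscape
#'
#' Executes, in order: landscape simulation, the three resistance layers
#' and their cumulative 1-10 surface, focal-node derivation (reach
#' midpoints, merged and snapped), the pairwise circuit solve with the
#' cumulative current map, least-cost-path ranking and corridor buffering,
#' and the Firth-regression validation against simulated snag-site
#' transits. All stage outputs land in `out_dir` as plain-text artifacts
#' (ESRI ASCII rasters, GeoJSON lines, CSV tables, JSON reports) plus a
#' `manifest.json` with the resolved configuration, per-stage timings and
#' artifact checksums. Deterministic for a fixed config seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the main in-memory results (nodes,
#'   circuit result, ranked paths, validation fit, manifest).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config = unclass_config(config),
                   package_version = as.character(
                     utils::packageVersion("bearcircuit")),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3))
    res
  }

  ls_cfg <- config$landscape

  # --- simulate -----------------------------------------------------------
  sim <- t_stage("simulate", {
    elevation <- generate_elevation(ls_cfg)
    land <- generate_land_mask(elevation, ls_cfg)
    landcover <- generate_landcover(elevation, ls_cfg)
    age <- generate_stand_age(landcover, ls_cfg)
    hydro <- generate_hydrology(elevation, ls_cfg)
    sites <- generate_snag_sites(ls_cfg, config$n_snag_sites, elevation)
    list(elevation = elevation, land = land, landcover = landcover,
         age = age, hydro = hydro, sites = sites)
  })
  write_ascii_grid(sim$elevation, file.path(out_dir, "elevation.asc"))
  write_ascii_grid(sim$land, file.path(out_dir, "land_mask.asc"))
  write_ascii_grid(sim$landcover, file.path(out_dir, "landcover.asc"))
  write_lines_geojson(sim$hydro$reaches, file.path(out_dir, "reaches.geojson"))
  utils::write.csv(drop_list_cols(sim$sites),
                   file.path(out_dir, "snag_sites.csv"), row.names = FALSE)
  say("simulate: %d x %d cells, %d streams, %d reaches, %d snag sites",
      nrow(sim$elevation$values), ncol(sim$elevation$values),
      nrow(sim$hydro$streams), nrow(sim$hydro$reaches), nrow(sim$sites))

  # --- resistance ---------------------------------------------------------
  cumres <- t_stage("resistance", {
    tri <- terrain_ruggedness_index(sim$elevation)
    tri_layer <- classify_continuous(tri, tri_scheme())
    lc_layer <- classify_landcover(sim$landcover, sim$age)
    dshore <- distance_to_shore(sim$land)
    w_layer <- classify_water(dshore, sim$land)
    combine_layers(tri_layer, lc_layer, w_layer)
  })
  write_ascii_grid(cumres, file.path(out_dir, "cumulative_resistance.asc"))
  say("resistance: cumulative surface over %d cells, range [%g, %g]",
      sum(!is.na(cumres$values)), min(cumres$values, na.rm = TRUE),
      max(cumres$values, na.rm = TRUE))

  # --- nodes --------------------------------------------------------------
  nodes <- t_stage("nodes", {
    mids <- reach_midpoints(sim$hydro)
    merged <- merge_nodes(mids, config$merge_radius_m)
    snap_to_grid(merged, cumres)
  })
  utils::write.csv(drop_list_cols(nodes), file.path(out_dir, "nodes.csv"),
                   row.names = FALSE)
  say("nodes: %d focal nodes -> %d unordered pairs", nrow(nodes),
      nrow(nodes) * (nrow(nodes) - 1) / 2)

  # --- circuit ------------------------------------------------------------
  graph <- build_graph(cumres)
  circuit <- t_stage("circuit", pairwise_all(graph, nodes))
  write_ascii_grid(circuit$cumulative_current,
                   file.path(out_dir, "cumulative_current.asc"))
  utils::write.csv(as.data.frame(circuit$R_eff),
                   file.path(out_dir, "effective_resistance.csv"))
  utils::write.csv(as.data.frame(circuit$G_eff),
                   file.path(out_dir, "effective_conductance.csv"))
  say("circuit: solved %d pairs over %d cells", circuit$n_pairs, graph$n)

  # --- lcp ----------------------------------------------------------------
  ranked <- t_stage("lcp", {
    cost <- current_to_cost(circuit$cumulative_current)
    paths <- fete_lcps(cost, nodes)
    rank_paths(paths, config$top_fraction)
  })
  corridors <- buffer_corridors(ranked, config$corridor_width_m)
  utils::write.csv(drop_list_cols(ranked), file.path(out_dir, "lcp_top.csv"),
                   row.names = FALSE)
  write_lines_geojson(
    tibble::tibble(reach_id = ranked$pair_id, species = NA_character_,
                   geometry = ranked$coords),
    file.path(out_dir, "lcp_top.geojson"))
  if (!is.null(corridors$mask))
    write_ascii_grid(corridors$mask, file.path(out_dir, "corridors.asc"))
  say("lcp: kept top %d paths; corridor area %.1f km2",
      nrow(ranked), corridors$area_m2 / 1e6)

  # --- validate -----------------------------------------------------------
  validation <- t_stage("validate", {
    site_graph <- graph
    sites_snapped <- snap_to_grid(sim$sites, cumres)
    site_circuit <- pairwise_all(site_graph, sites_snapped)
    det <- simulate_detections(sim$sites, config$detection,
                               derive_seed(config$seed, "detections"))
    transits <- build_transit_edges(det, sites_snapped)
    G <- site_circuit$G_eff
    transits$conductance <- G[cbind(match(transits$site_a, rownames(G)),
                                    match(transits$site_b, colnames(G)))]
    keep <- is.finite(transits$conductance)
    v <- validate_surface(transits[keep, ])
    list(transits = transits, detections = det, result = v)
  })
  utils::write.csv(validation$detections,
                   file.path(out_dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(validation$transits, file.path(out_dir, "transits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(validation$result$report,
                       file.path(out_dir, "firth_fit.json"),
                       digits = NA, auto_unbox = TRUE)
  say("validate: conductance OR %.3f, distance OR %.3f",
      validation$result$report$odds_ratio[2],
      validation$result$report$odds_ratio[3])

  # --- manifest -----------------------------------------------------------
  arts <- list.files(out_dir, full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  manifest$artifacts <- stats::setNames(
    as.list(unname(tools::md5sum(arts))), basename(arts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(nodes = nodes, circuit = circuit, ranked = ranked,
                 corridors = corridors, validation = validation,
                 manifest = manifest))
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$landscape <- unclass(out$landscape)
  out$detection <- unclass(out$detection)
  out
}

drop_list_cols <- function(df) {
  df[, !vapply(df, is.list, TRUE), drop = FALSE]
}

#' Write polylines as GeoJSON
#'
#' Minimal GeoJSON FeatureCollection writer for tables with a `geometry`
#' list-column of coordinate matrices (LineStrings); all other non-list
#' columns become feature properties.
#'
#' @param table tibble with a `geometry` list-column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lines_geojson <- function(table, path) {
  features <- lapply(seq_len(nrow(table)), function(k) {
    props <- as.list(drop_list_cols(table[k, , drop = FALSE]))
    coords <- table$geometry[[k]]
    list(type = "Feature", properties = props,
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(coords)),
                                              function(i) as.numeric(coords[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read polylines from GeoJSON
#'
#' @param path GeoJSON file written by [write_lines_geojson()].
#' @return Tibble with properties and a `geometry` list-column.
#' @export
read_lines_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    colnames(coords) <- c("x", "y")
    props <- lapply(f$properties, function(p) p %||% NA)
    tibble::as_tibble(c(props, list(geometry = list(coords))))
  })
  dplyr::bind_rows(rows)
}
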