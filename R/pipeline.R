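#' Default pipeline configuration
#'
#' A fully synthetic configuration: a seeded landscape, facility registry
#' with the four-level public/private structure, GPS trajectory survey,
#' full four-strata by three-scenario travel-time design, and 30/60/120
#' minute coverage thresholds.
#'
#' @param seed integer seed driving every synthetic block (mandatory for
#'   synthetic runs).
#' @param ... named overrides merged over the defaults (one level deep).
#' @return a named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = NULL, ...) {
  cfg <- list(
    seed = seed,
    synthetic = TRUE,
    grid = list(n_rows = 60, n_cols = 60, cell_size = 30,
                origin_x = 0, origin_y = 0),
    landscape = list(),
    population = list(),
    facilities = list(counts = list(hospital = c(10, 3),
                                    health_center = c(69, 6),
                                    medical_center = c(3, 45),
                                    clinic = c(2, 154)),
                      clustering = 1.5),
    trajectories = list(n_trips = 60, gps_noise_sd = 0, sampling_dt = 2),
    speeds = list(buffer = 20, max_gap = 30, outlier_cap = 120),
    strata = FACILITY_STRATA,
    scenarios = SCENARIOS,
    thresholds = c(30, 60, 120),
    connectivity = 8,
    out_dir = NULL)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

#' Read and validate a pipeline configuration file
#'
#' @param path YAML (or JSON) configuration document.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- pipeline_config(seed = cfg$seed)
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  validate_pipeline_config(base)
}

validate_pipeline_config <- function(cfg) {
  if (isTRUE(cfg$synthetic) &&
      (is.null(cfg$seed) || !is.finite(as.numeric(cfg$seed))))
    stop("config error: a seed is mandatory when synthetic inputs are used")
  if (!all(cfg$strata %in% FACILITY_STRATA))
    stop("config error: unknown stratum in ",
         paste(cfg$strata, collapse = ", "))
  if (!all(cfg$scenarios %in% SCENARIOS))
    stop("config error: unknown scenario in ",
         paste(cfg$scenarios, collapse = ", "))
  if (any(cfg$thresholds <= 0)) stop("config error: thresholds must be > 0")
  if (!cfg$connectivity %in% c(8, 16))
    stop("config error: connectivity must be 8 or 16")
  cfg
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full accessibility pipeline
#'
#' Executes the whole design from one configuration: generate (or load)
#' the landscape, estimate speeds from trajectories, build per-scenario
#' friction surfaces, accumulate travel time for every (stratum,
#' scenario) pair, and derive zonal, coverage, equiplot and urbanicity
#' tables. Deterministic given `(config, seed)`. When `out_dir` is set,
#' travel-time surfaces are written as ASCII grids and tables as CSV,
#' plus a JSON QC report (facility snap warnings, capped speed
#' observations, unreachable populated cells).
#'
#' @param config list from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir output directory (default `config$out_dir`; `NULL` for
#'   no files).
#' @return (invisibly) list with all inputs, the speed table, travel-time
#'   surfaces (`tt`, keyed `"stratum|scenario"`), and tables `zonal`,
#'   `coverage`, `equiplot`, `urbanicity`, `qc`.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  cfg <- validate_pipeline_config(config)
  qc <- list(warnings = character())
  note <- function(w) {
    qc$warnings <<- c(qc$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  g <- cfg$grid
  spec <- grid_spec(g$n_rows, g$n_cols, g$cell_size, g$origin_x, g$origin_y)

  if (isTRUE(cfg$synthetic)) {
    seed <- as.integer(cfg$seed)
    log_stage("synth", "generating landscape (seed ", seed, ")")
    land <- gen_landscape(spec, do.call(landscape_config, cfg$landscape),
                          seed)
    pru <- gen_population_rwi_urbanicity(
      spec, do.call(population_config, cfg$population), seed + 1L)
    fac <- gen_facilities(spec, cfg$facilities$counts,
                          clustering = cfg$facilities$clustering %||% 1,
                          seed = seed + 2L, pop = pru$pop,
                          roads = land$roads)
    log_stage("synth", "tracing ", cfg$trajectories$n_trips, " trips")
    trips <- gen_trajectories(land$roads, reference_road_speeds(),
                              n_trips = cfg$trajectories$n_trips,
                              gps_noise_sd = cfg$trajectories$gps_noise_sd,
                              sampling_dt = cfg$trajectories$sampling_dt,
                              seed = seed + 3L)
  } else {
    p <- cfg$paths
    if (is.null(p)) stop("config error: non-synthetic runs need a 'paths' block")
    log_stage("load", "reading inputs from configured paths")
    land <- list(dem = read_ascii_grid(p$dem, "dem"),
                 landcover = read_ascii_grid(p$landcover, "landcover"),
                 roads = read_roads_geojson(p$roads),
                 zones = read_zones_geojson(p$zones))
    pru <- list(pop = read_ascii_grid(p$pop, "wocba"),
                rwi = read_rwi_geojson(p$rwi),
                urbanicity = read_ascii_grid(p$urbanicity, "urbanicity"))
    fac <- read_facilities_geojson(p$facilities)
    trips <- if (!is.null(p$trajectories))
      read_trajectories_csv(p$trajectories) else NULL
  }

  log_stage("speeds", "estimating road-class speeds")
  speeds <- withCallingHandlers(
    if (!is.null(trips))
      estimate_speeds(trips, land$roads, buffer = cfg$speeds$buffer,
                      max_gap = cfg$speeds$max_gap,
                      outlier_cap = cfg$speeds$outlier_cap,
                      fallback = reference_road_speeds())
    else speed_table(rbind(as.data.frame(reference_road_speeds()),
                           as.data.frame(default_landcover_speeds()))),
    warning = note)
  qc$capped_observations <- attr(speeds, "qc")$capped_observations %||% 0L

  log_stage("friction", "rasterizing roads")
  road_raster <- rasterize_roads(land$roads, spec, speeds)

  log_stage("traveltime", length(cfg$strata) * length(cfg$scenarios),
            " travel-time surfaces")
  tt <- withCallingHandlers(
    run_matrix(road_raster, land$landcover, land$dem, speeds, fac,
               strata = cfg$strata, scenarios = cfg$scenarios,
               connectivity = cfg$connectivity),
    warning = note)

  log_stage("summaries", "zonal, coverage, equity, urbanicity tables")
  masked <- lapply(tt, mask_populated, pop = pru$pop)
  qc$unreachable_populated_cells <- vapply(
    masked, function(m) sum(is.na(m$values) & pru$pop$values > 0),
    numeric(1))

  zonal <- do.call(rbind, lapply(masked, zonal_stats, zones = land$zones,
                                 pop = pru$pop))
  cov <- do.call(rbind, lapply(masked, coverage, pop = pru$pop,
                               zones = land$zones,
                               thresholds = cfg$thresholds))
  rwi_cells <- match_rwi(masked[[1]], pru$rwi)
  assignment <- assign_quintiles(rwi_cells$values, pru$pop$values)
  eq_zones <- zone_set(Filter(function(z)
    z$zone_level %in% c("study_area", "departement"), land$zones$zones))
  eq <- do.call(rbind, lapply(masked, equiplot_table,
                              assignment = assignment, zones = eq_zones))
  urb <- do.call(rbind, lapply(masked, urbanicity_summary,
                               urbanicity = pru$urbanicity, pop = pru$pop))
  rownames(zonal) <- rownames(cov) <- rownames(eq) <- rownames(urb) <- NULL

  res <- list(spec = spec, landscape = land, population = pru$pop,
              rwi = pru$rwi, urbanicity = pru$urbanicity,
              facilities = fac, speeds = speeds, road_raster = road_raster,
              tt = tt, tt_masked = masked, zonal = zonal, coverage = cov,
              equiplot = eq, urbanicity_table = urb, qc = qc)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_stage("write", "outputs to ", out_dir)
    for (key in names(tt)) {
      fn <- file.path(out_dir,
                      paste0("tt_", gsub("\\|", "_", key), ".asc"))
      write_ascii_grid(tt[[key]], fn)
    }
    write_speed_table_csv(speeds, file.path(out_dir, "speeds.csv"))
    utils::write.csv(zonal, file.path(out_dir, "zonal.csv"),
                     row.names = FALSE)
    utils::write.csv(cov, file.path(out_dir, "coverage.csv"),
                     row.names = FALSE)
    utils::write.csv(eq, file.path(out_dir, "equiplot.csv"),
                     row.names = FALSE)
    utils::write.csv(urb, file.path(out_dir, "urbanicity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}
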