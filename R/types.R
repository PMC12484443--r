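ROAD_CLASSES <- c("trunk", "primary", "secondary", "tertiary",
                  "residential", "service", "unclassified", "others")

LANDCOVER_CLASSES <- c(water = 1L, trees = 2L, flooded_vegetation = 3L,
                       crops = 4L, built_area = 5L, rangeland = 6L,
                       bare_ground = 7L)

FACILITY_LEVELS <- c("hospital", "health_center", "medical_center", "clinic")
FACILITY_SECTORS <- c("public_government", "public_fbo", "private")
FACILITY_STRATA <- c("all", "public", "hospitals", "public_hospitals")
SCENARIOS <- c("minimum", "average", "maximum")

#' Closed vocabularies used across the pipeline
#'
#' Road classes follow the OSM highway hierarchy collapsed to eight classes
#' ("others" collects footways and similar pedestrian-speed ways). Land
#' cover uses a seven-class scheme with water as an absolute travel
#' barrier. Facilities carry a level (hospital down to clinic) and a sector
#' (government, faith-based — together the public sector — or private).
#'
#' @return a named list of character vectors: `road_classes`,
#'   `landcover_classes` (named integer codes), `facility_levels`,
#'   `facility_sectors`, `strata`, `scenarios`.
#' @export
accessim_vocab <- function() {
  list(road_classes = ROAD_CLASSES, landcover_classes = LANDCOVER_CLASSES,
       facility_levels = FACILITY_LEVELS, facility_sectors = FACILITY_SECTORS,
       strata = FACILITY_STRATA, scenarios = SCENARIOS)
}

#' Construct a classed road network
#'
#' @param segments list; each element a list with `coords` (matrix of >= 2
#'   xy vertices, planar metres), `road_class` (one of the eight classes in
#'   [accessim_vocab()]), `segment_id` (integer, unique).
#' @return object of class `road_network`.
#' @export
road_network <- function(segments) {
  for (s in segments) {
    if (!is.matrix(s$coords) || nrow(s$coords) < 2L)
      stop("each segment needs a coords matrix with >= 2 vertices")
    if (!s$road_class %in% ROAD_CLASSES)
      stop("unknown road class: ", s$road_class)
  }
  ids <- vapply(segments, function(s) as.integer(s$segment_id), integer(1))
  if (anyDuplicated(ids)) stop("segment_id values must be unique")
  structure(list(segments = segments), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cls <- vapply(x$segments, function(s) s$road_class, character(1))
  cat("<road_network>", length(x$segments), "segments\n")
  print(table(factor(cls, levels = ROAD_CLASSES)))
  invisible(x)
}

#' Construct a facility registry
#'
#' @param df data.frame with columns `x`, `y` (planar metres), `level`,
#'   `sector` (closed sets, see [accessim_vocab()]), `facility_id`.
#' @return data.frame of class `facility_registry`.
#' @export
facility_registry <- function(df) {
  stopifnot(all(c("x", "y", "level", "sector", "facility_id") %in% names(df)))
  if (!all(df$level %in% FACILITY_LEVELS))
    stop("unknown facility level(s): ",
         paste(setdiff(df$level, FACILITY_LEVELS), collapse = ", "))
  if (!all(df$sector %in% FACILITY_SECTORS))
    stop("unknown facility sector(s): ",
         paste(setdiff(df$sector, FACILITY_SECTORS), collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("facility_registry", "data.frame")
  df
}

#' Construct a set of analysis zones
#'
#' @param zones list; each element a list with `ring` (matrix of xy
#'   vertices of a simple polygon), `zone_id`, `zone_level` (e.g.
#'   "commune", "arrondissement", "departement", "health_zone",
#'   "study_area"). `zone_id` must be unique within each level.
#' @return object of class `zone_set`.
#' @export
zone_set <- function(zones) {
  lv <- vapply(zones, function(z) z$zone_level, character(1))
  id <- vapply(zones, function(z) as.character(z$zone_id), character(1))
  if (anyDuplicated(paste(lv, id)))
    stop("zone_id values must be unique within a zone_level")
  structure(list(zones = zones), class = "zone_set")
}

#' Subset a zone set by level
#' @param zones a `zone_set`.
#' @param level zone level to keep.
#' @return a `zone_set` with only that level's zones.
#' @export
zones_at_level <- function(zones, level) {
  zone_set(Filter(function(z) z$zone_level == level, zones$zones))
}

#' Construct a per-class speed table
#'
#' The core parameter object of the scenario engine: one row per road or
#' land-cover class with mean / min / max (and, for road classes estimated
#' from trajectories, sd and n) speeds in km/h. The three speed columns
#' define the three travel scenarios: minimum (worst case), average,
#' maximum (best case).
#'
#' @param df data.frame with columns `class_kind` ("road" or "landcover"),
#'   `class`, `mean`, `min`, `max`, and optionally `sd`, `n`.
#' @return data.frame of class `speed_table`.
#' @export
speed_table <- function(df) {
  stopifnot(all(c("class_kind", "class", "mean", "min", "max") %in% names(df)))
  if (!"sd" %in% names(df)) df$sd <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_integer_
  bad <- with(df, !(min <= mean & mean <= max))
  if (any(bad))
    stop("speed table violates min <= mean <= max for: ",
         paste(df$class[bad], collapse = ", "))
  if (any(df$sd < 0, na.rm = TRUE)) stop("sd must be nonnegative")
  rownames(df) <- NULL
  class(df) <- c("speed_table", "data.frame")
  df
}

#' Look up one scenario's speed for given classes
#'
#' @param table a `speed_table`.
#' @param kind "road" or "landcover".
#' @param classes character vector of class names.
#' @param scenario one of "minimum", "average", "maximum".
#' @return numeric vector of speeds in km/h; errors naming any class
#'   missing from the table.
#' @export
scenario_speed <- function(table, kind, classes, scenario = "average") {
  scenario <- match.arg(scenario, SCENARIOS)
  col <- c(minimum = "min", average = "mean", maximum = "max")[[scenario]]
  sub <- table[table$class_kind == kind, , drop = FALSE]
  idx <- match(classes, sub$class)
  if (anyNA(idx) && any(!is.na(classes)))
    stop("class(es) missing from speed table: ",
         paste(unique(classes[is.na(idx) & !is.na(classes)]), collapse = ", "))
  sub[[col]][idx]
}

#' Bundled land-cover travel speeds (km/h)
#'
#' Walking speeds over off-road terrain used when no local survey is
#' available, as applied in metropolitan accessibility studies in coastal
#' West Africa: water is an absolute barrier (0), flooded vegetation is
#' near-impassable (0.1), tree cover slows walking to 2.5, open and built
#' terrain allows 4-5 km/h. Columns min and max bound the minimum- and
#' maximum-speed scenarios.
#'
#' @return a `speed_table` with `class_kind == "landcover"`.
#' @export
default_landcover_speeds <- function() {
  speed_table(data.frame(
    class_kind = "landcover",
    class = c("water", "trees", "flooded_vegetation", "crops",
              "built_area", "rangeland", "bare_ground"),
    mean = c(0, 2.5, 0.1, 4.0, 5.0, 4.5, 5.0),
    min  = c(0, 2.0, 0.08, 3.6, 4.0, 4.05, 4.0),
    max  = c(0, 3.0, 0.12, 4.8, 6.0, 5.4, 6.0)))
}

#' Bundled reference road speeds (km/h)
#'
#' Per-class motorized speed distributions measured by geo-tracing journeys
#' across a dense West African metropolitan road network: congested urban
#' traffic keeps even trunk roads near 20 km/h on average. The "others"
#' class (footways, steps, living streets) is fixed at walking pace
#' (5.0 / 4.0 / 6.0) rather than estimated from vehicle traces. Useful as
#' generator ground truth and as a fallback when no trajectory survey is
#' supplied.
#'
#' @return a `speed_table` with `class_kind == "road"`.
#' @export
reference_road_speeds <- function() {
  speed_table(data.frame(
    class_kind = "road",
    class = ROAD_CLASSES,
    mean = c(20.4, 18.0, 15.1, 15.3, 12.6, 9.6, 17.1, 5.0),
    min  = c(6.2, 3.1, 4.4, 4.1, 0.84, 4.2, 6.2, 4.0),
    max  = c(38.0, 38.0, 30.0, 33.3, 38.0, 25.5, 32.0, 6.0),
    sd   = c(8.9, 9.0, 5.8, 8.5, 7.0, 4.1, 7.8, NA)))
}
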