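point_segment_dist <- function(px, py, ax, ay, bx, by) {
  # distance from points (px,py) to segment (a,b); vectorized over points
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else
    clamp(((px - ax) * dx + (py - ay) * dy) / len2, 0, 1)
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

polyline_dist <- function(px, py, coords) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(coords) - 1L))
    d <- pmin(d, point_segment_dist(px, py, coords[i, 1], coords[i, 2],
                                    coords[i + 1, 1], coords[i + 1, 2]))
  d
}

#' Match trajectory points to the nearest road segment
#'
#' Nearest-segment matching: each GPS point maps to the closest polyline
#' within `buffer` metres, or is left unmatched. Distance ties are broken
#' towards the smallest `segment_id`, so matching is deterministic.
#'
#' @param traj trajectory data.frame with `x`, `y`, `t`.
#' @param roads a `road_network` (non-empty).
#' @param buffer maximum matching distance in metres (> 0).
#' @return data.frame with one row per point: `point`, `segment_id`,
#'   `road_class`, `dist` (`NA` id/class where unmatched).
#' @export
match_to_road <- function(traj, roads, buffer = 20) {
  if (length(roads$segments) == 0) stop("road network is empty")
  if (buffer <= 0) stop("buffer must be positive")
  np <- nrow(traj)
  ids <- vapply(roads$segments, function(s) as.integer(s$segment_id),
                integer(1))
  ord <- order(ids)  # ascending id so the first minimum wins ties
  best <- rep(Inf, np)
  best_seg <- rep(NA_integer_, np)
  best_class <- rep(NA_character_, np)
  for (j in ord) {
    s <- roads$segments[[j]]
    d <- polyline_dist(traj$x, traj$y, s$coords)
    better <- d < best  # strict: earlier (smaller) id keeps exact ties
    best[better] <- d[better]
    best_seg[better] <- s$segment_id
    best_class[better] <- s$road_class
  }
  out <- best <= buffer
  data.frame(point = seq_len(np),
             segment_id = ifelse(out, best_seg, NA_integer_),
             road_class = ifelse(out, best_class, NA_character_),
             dist = ifelse(out, best, NA_real_))
}

#' Speeds from consecutive matched trajectory points
#'
#' Every consecutive pair of points matched to the same segment (or, with
#' `same_class_ok`, the same road class) yields one speed observation:
#' straight-line distance over elapsed time, in km/h. Pairs spanning an
#' unmatched point, exceeding `max_gap` seconds, or with zero elapsed time
#' (warned, not an error) are skipped.
#'
#' @param traj trajectory data.frame with `x`, `y`, `t` (strictly
#'   increasing) and `trip_id`.
#' @param matches output of [match_to_road()] for the same points.
#' @param max_gap largest allowed time gap between pair members, seconds.
#' @param same_class_ok accept pairs on different segments of one class.
#' @return data.frame of observations: `trip_id`, `segment_id`,
#'   `road_class`, `speed` (km/h), `dt` (s).
#' @export
point_pair_speeds <- function(traj, matches, max_gap = 30,
                              same_class_ok = TRUE) {
  n <- nrow(traj)
  if (n < 2) return(empty_obs())
  i <- seq_len(n - 1L); j <- i + 1L
  ok_match <- !is.na(matches$segment_id[i]) & !is.na(matches$segment_id[j])
  same <- matches$segment_id[i] == matches$segment_id[j]
  if (same_class_ok)
    same <- same | (matches$road_class[i] == matches$road_class[j])
  dt <- traj$t[j] - traj$t[i]
  zero_dt <- ok_match & same & dt == 0
  if (any(zero_dt, na.rm = TRUE))
    warning(sum(zero_dt, na.rm = TRUE),
            " point pair(s) with zero elapsed time skipped")
  keep <- which(ok_match & same & dt > 0 & dt <= max_gap)
  if (!length(keep)) return(empty_obs())
  dist <- sqrt((traj$x[keep + 1L] - traj$x[keep])^2 +
                 (traj$y[keep + 1L] - traj$y[keep])^2)
  trip <- if (!is.null(traj$trip_id)) traj$trip_id[keep]
  else rep(attr(traj, "trip_id") %||% NA, length(keep))
  data.frame(trip_id = trip, segment_id = matches$segment_id[keep],
             road_class = matches$road_class[keep],
             speed = dist / dt[keep] * 3.6, dt = dt[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_obs <- function() {
  data.frame(trip_id = integer(), segment_id = integer(),
             road_class = character(), speed = numeric(), dt = numeric())
}

#' Aggregate speed observations into a per-class speed table
#'
#' Per road class: mean, min, max and sample sd (n-1 denominator) of all
#' observations at or below `outlier_cap` (a GPS-glitch guard; capped
#' observations are counted in the `qc` attribute). Land-cover walking
#' speeds are not estimated from traces: they are copied from the supplied
#' fixed map, [default_landcover_speeds()] by default. The "others" road
#' class (footways etc.) likewise takes fixed walking-pace values rather
#' than trace estimates.
#'
#' @param obs observation data.frame from [point_pair_speeds()] (rows from
#'   several trips concatenated).
#' @param landcover_speeds a `speed_table` of land-cover rows to append.
#' @param outlier_cap drop observations above this speed, km/h.
#' @param required_classes road classes that must have observations (e.g.
#'   every class present in the study network); a class listed here with
#'   zero observations is an error naming the class, unless it appears in
#'   `fallback`.
#' @param fallback optional `speed_table` rows (class_kind "road")
#'   supplying speeds for required classes without observations.
#' @param others_fixed mean/min/max used for the "others" class.
#' @return a `speed_table` with road and land-cover rows; attribute `qc`
#'   records the number of capped observations.
#' @export
aggregate_speed_table <- function(obs,
                                  landcover_speeds = default_landcover_speeds(),
                                  outlier_cap = 120,
                                  required_classes = NULL,
                                  fallback = NULL,
                                  others_fixed = c(mean = 5, min = 4, max = 6)) {
  capped <- sum(obs$speed > outlier_cap)
  obs <- obs[obs$speed <= outlier_cap, , drop = FALSE]
  have <- split(obs$speed, obs$road_class)
  rows <- lapply(names(have), function(cl) {
    v <- have[[cl]]
    data.frame(class_kind = "road", class = cl, mean = mean(v),
               min = min(v), max = max(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  })
  road <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class_kind = character(), class = character(),
               mean = numeric(), min = numeric(), max = numeric(),
               sd = numeric(), n = integer())

  need <- setdiff(setdiff(required_classes %||% character(), "others"),
                  road$class)
  if (length(need)) {
    fb <- if (!is.null(fallback))
      fallback[fallback$class_kind == "road" & fallback$class %in% need, ,
               drop = FALSE]
    else NULL
    still <- setdiff(need, if (is.null(fb)) character() else fb$class)
    if (length(still))
      stop("no speed observations and no fallback for road class(es): ",
           paste(still, collapse = ", "))
    fb$n <- 0L
    road <- rbind(road, fb[names(road)])
  }
  if (is.null(required_classes) || "others" %in% required_classes ||
      !nrow(road)) {
    road <- rbind(road,
                  data.frame(class_kind = "road", class = "others",
                             mean = others_fixed[["mean"]],
                             min = others_fixed[["min"]],
                             max = others_fixed[["max"]], sd = NA_real_,
                             n = 0L))
  }
  road <- road[!duplicated(road$class), , drop = FALSE]
  lc <- as.data.frame(landcover_speeds)
  out <- speed_table(rbind(road[names(lc)], lc))
  attr(out, "qc") <- list(capped_observations = capped)
  out
}

#' End-to-end speed survey: trajectories to speed table
#'
#' Convenience wrapper: match every trajectory, compute point-pair speeds,
#' and aggregate, requiring coverage of every class present in `roads`.
#'
#' @param trajectories list of trajectory data.frames.
#' @inheritParams match_to_road
#' @inheritParams point_pair_speeds
#' @inheritParams aggregate_speed_table
#' @return a `speed_table`.
#' @export
estimate_speeds <- function(trajectories, roads, buffer = 20, max_gap = 30,
                            landcover_speeds = default_landcover_speeds(),
                            outlier_cap = 120, fallback = NULL) {
  obs <- do.call(rbind, lapply(trajectories, function(tr) {
    point_pair_speeds(tr, match_to_road(tr, roads, buffer), max_gap = max_gap)
  }))
  present <- unique(vapply(roads$segments, function(s) s$road_class,
                           character(1)))
  aggregate_speed_table(obs, landcover_speeds, outlier_cap,
                        required_classes = union(present, "others"),
                        fallback = fallback)
}
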