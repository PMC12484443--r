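#' Default configuration for the synthetic landscape generator
#'
#' The defaults sketch a coastal metropolitan study area: mostly built-up
#' land with water and flooded vegetation along the field minima, a road
#' hierarchy dominated by residential streets, gentle terrain, and a
#' rectangular administrative partition at four levels.
#'
#' @param ... named overrides merged over the defaults (one level deep).
#' @return a named list understood by [gen_landscape()].
#' @export
landscape_config <- function(...) {
  cfg <- list(
    landcover_fractions = c(water = 0.08, trees = 0.10,
                            flooded_vegetation = 0.04, crops = 0.15,
                            built_area = 0.45, rangeland = 0.13,
                            bare_ground = 0.05),
    road_counts = c(trunk = 2, primary = 3, secondary = 3, tertiary = 4,
                    residential = 8, service = 3, unclassified = 2,
                    others = 0),
    zone_levels = list(study_area = c(1, 1), departement = c(3, 1),
                       health_zone = c(4, 2), commune = c(5, 1),
                       arrondissement = c(7, 6)),
    dem = list(base = 10, n_bumps = 4, amp = c(5, 40), sigma_frac = c(0.1, 0.3))
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

gaussian_bump_field <- function(grid, n_bumps, amp, sigma_frac, base = 0) {
  ext <- grid_extent(grid)
  w <- ext["xmax"] - ext["xmin"]; h <- ext["ymax"] - ext["ymin"]
  bumps <- data.frame(
    cx = stats::runif(n_bumps, ext["xmin"], ext["xmax"]),
    cy = stats::runif(n_bumps, ext["ymin"], ext["ymax"]),
    a = stats::runif(n_bumps, amp[1], amp[2]),
    sigma = stats::runif(n_bumps, sigma_frac[1], sigma_frac[2]) * min(w, h))
  cc <- cell_centers(grid)
  v <- rep(base, nrow(cc))
  for (i in seq_len(n_bumps))
    v <- v + bumps$a[i] *
      exp(-((cc$x - bumps$cx[i])^2 + (cc$y - bumps$cy[i])^2) /
            (2 * bumps$sigma[i]^2))
  m <- matrix(v, grid$n_rows, grid$n_cols)
  attr(m, "bumps") <- bumps
  m
}

#' Generate a synthetic study landscape
#'
#' Produces an internally consistent DEM, land-cover raster, classed road
#' network and zone partition on one grid, fully determined by
#' `(spec, config, seed)`.
#'
#' The DEM is a sum of Gaussian bumps (parameters retained in the `bumps`
#' attribute, so slopes have a closed form for tests). Land cover is
#' assigned by ranking a second smooth random field and slicing the ranked
#' cells so the configured class fractions are honoured exactly (up to one
#' cell): the wettest classes (water, flooded vegetation) occupy the field
#' minima, built area the maxima, giving contiguous patches. Roads are
#' built sequentially — the first segment spans the extent, every later
#' segment starts on an existing road — so the network is connected. Zones
#' are rectangular partitions of the extent at each configured level.
#'
#' @param spec a [grid_spec()].
#' @param config list from [landscape_config()]; `landcover_fractions`
#'   must sum to 1.
#' @param seed integer seed; mandatory, generation is a pure function of
#'   `(spec, config, seed)`.
#' @return list with `dem`, `landcover` (both [acc_raster()]), `roads`
#'   (`road_network`), `zones` (`zone_set`).
#' @export
gen_landscape <- function(spec, config = landscape_config(), seed) {
  if (missing(seed) || !is.finite(seed))
    stop("seed is required: generation must be reproducible")
  fr <- config$landcover_fractions
  if (abs(sum(fr) - 1) > 1e-8)
    stop("landcover_fractions must sum to 1 (got ", sum(fr), ")")
  if (!all(names(fr) %in% names(LANDCOVER_CLASSES)))
    stop("unknown land-cover class in fractions: ",
         paste(setdiff(names(fr), names(LANDCOVER_CLASSES)), collapse = ", "))

  set.seed(as.integer(seed))
  dm <- config$dem
  dem_m <- gaussian_bump_field(spec, dm$n_bumps, dm$amp, dm$sigma_frac,
                               base = dm$base)
  dem <- acc_raster(spec, dem_m, layer = "dem")
  attr(dem, "bumps") <- attr(dem_m, "bumps")

  # wet-to-dry ordering along the ranked field gives contiguous patches
  lc_field <- gaussian_bump_field(spec, max(3L, dm$n_bumps), c(1, 10),
                                  c(0.08, 0.25))
  order_classes <- c("water", "flooded_vegetation", "trees", "crops",
                     "rangeland", "bare_ground", "built_area")
  order_classes <- order_classes[order_classes %in% names(fr)]
  n <- spec$n_rows * spec$n_cols
  counts <- floor(fr[order_classes] * n)
  rem <- n - sum(counts)
  if (rem > 0) {  # leftover cells to the largest fractional parts
    fp <- fr[order_classes] * n - counts
    add <- order(fp, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  rk <- rank(as.vector(lc_field), ties.method = "first")
  code <- integer(n)
  lo <- 0
  for (cl in order_classes) {
    k <- counts[[cl]]
    if (k > 0) code[rk > lo & rk <= lo + k] <- LANDCOVER_CLASSES[[cl]]
    lo <- lo + k
  }
  landcover <- acc_raster(spec, matrix(code, spec$n_rows, spec$n_cols),
                          layer = "landcover")

  roads <- gen_road_network(spec, config$road_counts)
  zones <- gen_zone_partition(spec, config$zone_levels)
  list(dem = dem, landcover = landcover, roads = roads, zones = zones)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

gen_road_network <- function(spec, road_counts) {
  ext <- grid_extent(spec)
  segs <- list(); sid <- 0L
  all_vertices <- NULL
  jitter_amp <- (ext["ymax"] - ext["ymin"]) * 0.1
  for (cl in ROAD_CLASSES) {
    k <- if (cl %in% names(road_counts)) road_counts[[cl]] else 0
    for (i in seq_len(k)) {
      sid <- sid + 1L
      if (is.null(all_vertices)) {
        # spine spanning the extent west to east, anchored on a row centre
        xs <- seq(ext["xmin"], ext["xmax"], length.out = 6)
        ymid <- ext["ymin"] + (floor(spec$n_rows / 2) + 0.5) * spec$cell_size
        ys <- ymid + c(0, stats::rnorm(4, 0, jitter_amp), 0)
        coords <- cbind(xs, clamp(ys, ext["ymin"], ext["ymax"]))
      } else {
        start <- all_vertices[sample.int(nrow(all_vertices), 1), ]
        end <- c(stats::runif(1, ext["xmin"], ext["xmax"]),
                 stats::runif(1, ext["ymin"], ext["ymax"]))
        mid <- (start + end) / 2 + stats::rnorm(2, 0, jitter_amp / 2)
        coords <- rbind(start, clamp(mid, ext[c("xmin", "ymin")],
                                     ext[c("xmax", "ymax")]), end)
      }
      dimnames(coords) <- NULL
      segs[[sid]] <- list(coords = coords, road_class = cl, segment_id = sid)
      all_vertices <- rbind(all_vertices, coords)
    }
  }
  road_network(segs)
}

gen_zone_partition <- function(spec, zone_levels) {
  ext <- grid_extent(spec)
  zones <- list()
  for (lv in names(zone_levels)) {
    nb <- zone_levels[[lv]]
    xb <- seq(ext["xmin"], ext["xmax"], length.out = nb[1] + 1)
    yb <- seq(ext["ymin"], ext["ymax"], length.out = nb[2] + 1)
    zid <- 0L
    for (j in seq_len(nb[2])) for (i in seq_len(nb[1])) {
      zid <- zid + 1L
      ring <- cbind(c(xb[i], xb[i + 1], xb[i + 1], xb[i], xb[i]),
                    c(yb[j], yb[j], yb[j + 1], yb[j + 1], yb[j]))
      zones[[length(zones) + 1L]] <-
        list(ring = ring, zone_id = sprintf("%s_%02d", lv, zid),
             zone_level = lv)
    }
  }
  zone_set(zones)
}

split_public_sector <- function(level_public_counts, fbo_share = 1 / 6) {
  # largest-remainder allocation of the faith-based share per level
  raw <- level_public_counts * fbo_share
  fbo <- floor(raw)
  rem <- round(sum(raw)) - sum(fbo)
  if (rem > 0) {
    add <- order(raw - fbo, decreasing = TRUE)[seq_len(rem)]
    fbo[add] <- fbo[add] + 1
  }
  fbo <- pmin(fbo, level_public_counts)
  fbo
}

#' Generate a facility registry with configurable level/sector structure
#'
#' Places the exact requested number of facilities per level and sector
#' group. The public group is split between government-managed and
#' faith-based facilities at roughly 5:1 (largest-remainder per level).
#' Facility locations are drawn over grid cells with probability
#' proportional to `weight^clustering`, where the weight is the supplied
#' population raster (uniform if absent): `clustering = 0` is uniform
#' placement, larger values concentrate facilities in dense areas. When a
#' road network is supplied, candidate cells are restricted to cells on or
#' adjacent to a road, so no facility is stranded off-network.
#'
#' @param spec a [grid_spec()].
#' @param counts named list `level -> c(public, private)` counts; at least
#'   one facility in total.
#' @param clustering nonnegative exponent on the placement weight.
#' @param seed integer seed (mandatory).
#' @param pop optional [acc_raster()] of population used as placement
#'   weight.
#' @param roads optional `road_network`; restricts placement to road-
#'   adjacent cells.
#' @return a `facility_registry` with facilities at cell centres.
#' @export
gen_facilities <- function(spec, counts, clustering = 1, seed, pop = NULL,
                           roads = NULL) {
  if (missing(seed) || !is.finite(seed)) stop("seed is required")
  if (!all(names(counts) %in% FACILITY_LEVELS))
    stop("unknown facility level(s): ",
         paste(setdiff(names(counts), FACILITY_LEVELS), collapse = ", "))
  tot <- sum(vapply(counts, sum, numeric(1)))
  if (tot < 1) stop("at least one facility is required")
  set.seed(as.integer(seed))

  n <- spec$n_rows * spec$n_cols
  w <- if (is.null(pop)) rep(1, n) else {
    check_same_grid(spec, pop)
    pmax(as.vector(pop$values), 0) + 1e-9
  }
  w <- w^clustering
  if (!is.null(roads)) {
    rr <- rasterize_roads(roads, spec)
    on_road <- !is.na(rr$values)
    near <- on_road
    # dilate by one cell so "adjacent to a road" qualifies
    near[-1, ] <- near[-1, ] | on_road[-spec$n_rows, ]
    near[-spec$n_rows, ] <- near[-spec$n_rows, ] | on_road[-1, ]
    near[, -1] <- near[, -1] | on_road[, -spec$n_cols]
    near[, -spec$n_cols] <- near[, -spec$n_cols] | on_road[, -1]
    w[!as.vector(near)] <- 0
    if (all(w == 0)) stop("no road-adjacent cells available for facilities")
  }

  pub <- vapply(counts, function(ct) ct[1], numeric(1))
  priv <- vapply(counts, function(ct) ct[2], numeric(1))
  fbo <- split_public_sector(pub)
  gov <- pub - fbo

  cc <- cell_centers(spec)
  rows <- list()
  for (lv in names(counts)) {
    for (sec in c("public_government", "public_fbo", "private")) {
      k <- switch(sec, public_government = gov[[lv]], public_fbo = fbo[[lv]],
                  private = priv[[lv]])
      if (k == 0) next
      idx <- sample.int(n, k, replace = TRUE, prob = w)
      rows[[length(rows) + 1L]] <-
        data.frame(x = cc$x[idx], y = cc$y[idx], level = lv, sector = sec)
    }
  }
  df <- do.call(rbind, rows)
  df$facility_id <- seq_len(nrow(df))
  facility_registry(df)
}

#' Generate population, wealth-sample and urbanicity layers
#'
#' Population (women of childbearing age, WoCBA) is a mixture of Gaussian
#' settlement kernels over a uniform background, rescaled so the raster
#' sums exactly to `total_wocba`. RWI sample points sit on a regular
#' lattice with the configured spacing; each point's wealth score is a
#' monotone spatial gradient (ground truth kept in the `gradient`
#' attribute) plus independent Gaussian noise. Urbanicity bands come from
#' thresholding a kernel-smoothed population density at the configured
#' quantiles — band k cells are denser than every cell of band k-1, by
#' construction.
#'
#' @param spec a [grid_spec()].
#' @param config list with elements `total_wocba`, `n_centres`,
#'   `centre_sigma_frac`, `background`, `rwi = list(spacing, noise_sd,
#'   gradient)` (gradient in score units across the extent, west to east),
#'   `urbanicity = list(bands, quantiles)`.
#' @param seed integer seed (mandatory).
#' @return list with `pop`, `urbanicity` ([acc_raster()]; band codes
#'   1 = least dense, with level names in the `bands` attribute),
#'   `rwi` (data.frame x, y, rwi with attributes `gradient`, `noise_sd`),
#'   and `density` (the smoothed field the bands were cut from).
#' @export
gen_population_rwi_urbanicity <- function(spec, config = population_config(),
                                          seed) {
  if (missing(seed) || !is.finite(seed)) stop("seed is required")
  if (config$total_wocba <= 0) stop("total_wocba must be positive")
  set.seed(as.integer(seed))
  ext <- grid_extent(spec)

  field <- gaussian_bump_field(spec, config$n_centres, c(5, 20),
                               config$centre_sigma_frac,
                               base = config$background)
  wocba <- field / sum(field) * config$total_wocba
  pop <- acc_raster(spec, wocba, layer = "wocba")
  attr(pop, "centres") <- attr(field, "bumps")

  sp <- config$rwi$spacing
  if (sp <= spec$cell_size)
    stop("rwi spacing must exceed the cell size")
  xs <- seq(ext["xmin"] + sp / 2, ext["xmax"], by = sp)
  ys <- seq(ext["ymin"] + sp / 2, ext["ymax"], by = sp)
  if (length(xs) * length(ys) < 5)
    stop("rwi spacing too large: fewer than 5 points fit the extent ",
         "(quintiles need >= 5)")
  pts <- expand.grid(x = xs, y = ys)
  grad <- config$rwi$gradient
  pts$rwi <- grad * (pts$x - ext["xmin"]) / (ext["xmax"] - ext["xmin"]) +
    stats::rnorm(nrow(pts), 0, config$rwi$noise_sd)
  attr(pts, "gradient") <- grad
  attr(pts, "noise_sd") <- config$rwi$noise_sd

  dens <- smooth_raster(wocba, radius = config$urbanicity$smooth_radius)
  qs <- config$urbanicity$quantiles
  brks <- unique(c(-Inf, stats::quantile(dens, probs = qs), Inf))
  band <- matrix(as.integer(cut(dens, breaks = brks)),
                 spec$n_rows, spec$n_cols)
  urb <- acc_raster(spec, band, layer = "urbanicity")
  attr(urb, "bands") <- config$urbanicity$bands[seq_len(max(band))]
  list(pop = pop, rwi = pts, urbanicity = urb,
       density = acc_raster(spec, dens, layer = "density"))
}

#' Default configuration for [gen_population_rwi_urbanicity()]
#'
#' @param ... named overrides merged over the defaults.
#' @return a named list.
#' @export
population_config <- function(...) {
  cfg <- list(
    total_wocba = 50000,
    n_centres = 3, centre_sigma_frac = c(0.08, 0.2), background = 0.3,
    rwi = list(spacing = 240, noise_sd = 0.1, gradient = 1.0),
    urbanicity = list(
      bands = c("very_low_density", "low_density", "village", "suburb",
                "town", "dense_town", "city"),
      quantiles = c(0.3, 0.5, 0.65, 0.8, 0.9, 0.97),
      smooth_radius = 3))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

smooth_raster <- function(m, radius = 3) {
  # separable box smoother, edge-renormalized
  k <- 2 * radius + 1
  pad_rows <- function(x) rbind(matrix(0, radius, ncol(x)), x,
                                matrix(0, radius, ncol(x)))
  run <- function(x) {
    cs <- apply(pad_rows(x), 2, cumsum)
    (cs[seq(k, nrow(cs)), , drop = FALSE] -
       rbind(0, cs[seq_len(nrow(cs) - k), , drop = FALSE]))
  }
  ones <- matrix(1, nrow(m), ncol(m))
  num <- t(run(t(run(m))))
  den <- t(run(t(run(ones))))
  num / den
}

#' Generate GPS trajectories along the road network with known speeds
#'
#' Each trip follows one randomly chosen road segment end-to-end at that
#' class's ground-truth mean speed (optionally perturbed per trip),
#' sampled at a fixed interval, with independent Gaussian positional noise
#' per coordinate — the observation model of a phone/tablet geo-tracing
#' survey.
#'
#' @param roads a `road_network`; `truth` must cover every class present.
#' @param truth a `speed_table` providing the ground-truth mean speed per
#'   road class (km/h).
#' @param n_trips number of trips to simulate (>= 1).
#' @param gps_noise_sd positional noise standard deviation, metres.
#' @param sampling_dt sampling interval in seconds (> 0).
#' @param seed integer seed (mandatory).
#' @param speed_jitter_sd per-trip speed perturbation sd, km/h (default 0:
#'   trips move exactly at the class truth).
#' @return list of trajectory data.frames (`trip_id`, `x`, `y`, `t`) with
#'   attributes `segment_id`, `road_class`, `true_speed_kmh`.
#' @export
gen_trajectories <- function(roads, truth, n_trips, gps_noise_sd = 0,
                             sampling_dt = 1, seed, speed_jitter_sd = 0) {
  if (missing(seed) || !is.finite(seed)) stop("seed is required")
  if (sampling_dt <= 0) stop("sampling_dt must be positive")
  if (n_trips < 1) stop("n_trips must be >= 1")
  present <- unique(vapply(roads$segments, function(s) s$road_class,
                           character(1)))
  covered <- truth$class[truth$class_kind == "road"]
  if (!all(present %in% covered))
    stop("truth speed table missing road class(es): ",
         paste(setdiff(present, covered), collapse = ", "))
  set.seed(as.integer(seed))

  out <- vector("list", n_trips)
  for (trip in seq_len(n_trips)) {
    seg <- roads$segments[[sample.int(length(roads$segments), 1)]]
    v_kmh <- scenario_speed(truth, "road", seg$road_class, "average")
    if (speed_jitter_sd > 0)
      v_kmh <- max(0.5, v_kmh + stats::rnorm(1, 0, speed_jitter_sd))
    v <- v_kmh / 3.6
    d <- sqrt(rowSums(diff(seg$coords)^2))
    cum <- c(0, cumsum(d))
    total_t <- cum[length(cum)] / v
    times <- seq(0, total_t, by = sampling_dt)
    if (times[length(times)] < total_t) times <- c(times, total_t)
    s <- times * v
    x <- stats::approx(cum, seg$coords[, 1], xout = s, ties = "ordered",
                       rule = 2)$y
    y <- stats::approx(cum, seg$coords[, 2], xout = s, ties = "ordered",
                       rule = 2)$y
    if (gps_noise_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, gps_noise_sd)
      y <- y + stats::rnorm(length(y), 0, gps_noise_sd)
    }
    tr <- data.frame(trip_id = trip, x = x, y = y, t = times)
    attr(tr, "segment_id") <- seg$segment_id
    attr(tr, "road_class") <- seg$road_class
    attr(tr, "true_speed_kmh") <- v_kmh
    out[[trip]] <- tr
  }
  out
}
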