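# Small in-code fixtures shared across test files.

make_speed_surface <- function(kmh, walking = TRUE, cell = 30,
                               scenario = "average", origin = c(0, 0)) {
  kmh <- as.matrix(kmh)
  g <- grid_spec(nrow(kmh), ncol(kmh), cell_size = cell,
                 origin_x = origin[1], origin_y = origin[2])
  if (length(walking) == 1L) walking <- matrix(walking, nrow(kmh), ncol(kmh))
  structure(list(grid = g, speed = kmh / 3.6, is_walking = walking,
                 scenario = scenario),
            class = "speed_raster")
}

registry_at_cells <- function(g, rows, cols, level = "hospital",
                              sector = "public_government") {
  cs <- g$cell_size
  facility_registry(data.frame(
    x = g$origin_x + (cols - 0.5) * cs,
    y = g$origin_y + (g$n_rows - rows + 0.5) * cs,
    level = level, sector = sector,
    facility_id = seq_along(rows)))
}

straight_segment <- function(x0, y0, x1, y1, class, id) {
  list(coords = cbind(c(x0, x1), c(y0, y1)), road_class = class,
       segment_id = id)
}

# One straight segment per road class on a common extent; used for exact
# speed-recovery checks (no corners, so point-pair speeds are exact).
straight_class_network <- function(length_m = 2000, spacing = 200) {
  classes <- setdiff(accessim_vocab()$road_classes, "others")
  segs <- lapply(seq_along(classes), function(i)
    straight_segment(0, i * spacing, length_m, i * spacing, classes[i], i))
  road_network(segs)
}

octile_distance <- function(r0, c0, r1, c1, cell) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  cell * (abs(dr - dc) + sqrt(2) * pmin(dr, dc))
}

small_landscape <- function(seed, n = 30) {
  spec <- grid_spec(n, n, cell_size = 30)
  cfg <- landscape_config(
    zone_levels = list(study_area = c(1, 1), departement = c(3, 1),
                       commune = c(3, 2)))
  land <- gen_landscape(spec, cfg, seed = seed)
  pru <- gen_population_rwi_urbanicity(
    spec, population_config(total_wocba = 5000,
                            rwi = list(spacing = 120, noise_sd = 0.05,
                                       gradient = 1)),
    seed = seed + 1)
  fac <- gen_facilities(
    spec, counts = list(hospital = c(2, 1), health_center = c(4, 2),
                        clinic = c(1, 4)),
    clustering = 1, seed = seed + 2, pop = pru$pop, roads = land$roads)
  c(land, pru, list(facilities = fac, spec = spec))
}
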