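spec20 <- grid_spec(20, 20, cell_size = 30)

test_that("landscape generation is deterministic and seed-mandatory", {
  a <- gen_landscape(spec20, landscape_config(), seed = 7)
  b <- gen_landscape(spec20, landscape_config(), seed = 7)
  expect_identical(a$dem$values, b$dem$values)
  expect_identical(a$landcover$values, b$landcover$values)
  expect_identical(lapply(a$roads$segments, `[[`, "coords"),
                   lapply(b$roads$segments, `[[`, "coords"))
  c_ <- gen_landscape(spec20, landscape_config(), seed = 8)
  expect_false(identical(a$dem$values, c_$dem$values))
  expect_error(gen_landscape(spec20, landscape_config()), "seed")
})

test_that("land-cover class fractions are honoured", {
  fr0 <- c(water = 0, trees = 0.2, flooded_vegetation = 0, crops = 0.2,
           built_area = 0.4, rangeland = 0.1, bare_ground = 0.1)
  land <- gen_landscape(spec20, landscape_config(landcover_fractions = fr0),
                        seed = 3)
  water_code <- accessim_vocab()$landcover_classes[["water"]]
  expect_equal(sum(land$landcover$values == water_code), 0)

  spec100 <- grid_spec(100, 100)
  fr <- c(water = 0.1, trees = 0.1, flooded_vegetation = 0.05, crops = 0.2,
          built_area = 0.35, rangeland = 0.1, bare_ground = 0.1)
  land2 <- gen_landscape(spec100, landscape_config(landcover_fractions = fr),
                         seed = 3)
  share <- mean(land2$landcover$values == water_code)
  expect_gte(share, 0.08)
  expect_lte(share, 0.12)

  bad <- fr; bad[["water"]] <- 0.5
  expect_error(gen_landscape(spec20,
                             landscape_config(landcover_fractions = bad),
                             seed = 1),
               "sum to 1")
})

test_that("roads and zones stay inside and partition the extent", {
  land <- gen_landscape(spec20, landscape_config(), seed = 11)
  ext <- grid_extent(spec20)
  for (s in land$roads$segments) {
    expect_true(all(s$coords[, 1] >= ext["xmin"] - 1e-9 &
                      s$coords[, 1] <= ext["xmax"] + 1e-9))
    expect_true(all(s$coords[, 2] >= ext["ymin"] - 1e-9 &
                      s$coords[, 2] <= ext["ymax"] + 1e-9))
  }
  comm <- zones_at_level(land$zones, "commune")
  memb <- zone_membership(comm, spec20)
  expect_false(anyNA(memb))  # partition: every cell in exactly one commune
})

test_that("facility generator reproduces the requested registry structure", {
  counts <- list(hospital = c(10, 3), health_center = c(69, 6),
                 medical_center = c(3, 45), clinic = c(2, 154))
  reg <- gen_facilities(spec20, counts, clustering = 1, seed = 5)
  expect_equal(nrow(reg), 292)
  expect_equal(sum(reg$sector != "private"), 84)
  expect_equal(sum(reg$level == "hospital"), 13)
  expect_equal(nrow(select_stratum(reg, "public_hospitals")), 10)
  expect_equal(nrow(select_stratum(reg, "hospitals")), 13)

  one <- gen_facilities(spec20, list(hospital = c(1, 0)), seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$level, "hospital")
  expect_match(one$sector, "^public")

  expect_error(gen_facilities(spec20, list(hospital = c(0, 0)), seed = 1),
               "at least one")
  ext <- grid_extent(spec20)
  expect_true(all(reg$x > ext["xmin"] & reg$x < ext["xmax"] &
                    reg$y > ext["ymin"] & reg$y < ext["ymax"]))
})

test_that("facility clustering follows population density", {
  set.seed(1)
  pop <- acc_raster(spec20, matrix(0.01, 20, 20))
  pop$values[1:5, 1:5] <- 10  # dense block in the north-west
  counts <- list(clinic = c(50, 50))
  reg <- gen_facilities(spec20, counts, clustering = 3, seed = 9, pop = pop)
  rc <- xy_to_cell(spec20, reg$x, reg$y)
  expect_gt(mean(rc$row <= 5 & rc$col <= 5), 0.8)
})

test_that("population conserves the configured total and RWI keeps truth", {
  pru <- gen_population_rwi_urbanicity(
    spec20, population_config(total_wocba = 10000), seed = 2)
  expect_lt(abs(sum(pru$pop$values) - 10000) / 10000, 0.001)
  expect_true(all(pru$pop$values >= 0))

  flat <- gen_population_rwi_urbanicity(
    spec20, population_config(rwi = list(spacing = 100, noise_sd = 0,
                                         gradient = 2)),
    seed = 2)
  byx <- flat$rwi[order(flat$rwi$x), ]
  expect_true(all(diff(tapply(byx$rwi, byx$x, unique)) > 0))
  expect_equal(attr(flat$rwi, "gradient"), 2)

  expect_error(gen_population_rwi_urbanicity(
    spec20, population_config(rwi = list(spacing = 500, noise_sd = 0,
                                         gradient = 1)),
    seed = 2), "fewer than 5")
  expect_error(gen_population_rwi_urbanicity(
    spec20, population_config(rwi = list(spacing = 20, noise_sd = 0,
                                         gradient = 1)),
    seed = 2), "cell size")
})

test_that("urbanicity bands are density-ordered by construction", {
  pru <- gen_population_rwi_urbanicity(spec20, population_config(), seed = 4)
  band <- pru$urbanicity$values
  dens <- pru$density$values
  top <- max(band)
  for (b in seq_len(top - 1))
    expect_gte(min(dens[band == top]), max(dens[band == b]))
})

test_that("trajectories move at ground-truth speed with exact sampling", {
  rn <- road_network(list(straight_segment(0, 0, 1000, 0, "trunk", 1)))
  truth <- reference_road_speeds()
  tr <- gen_trajectories(rn, truth, n_trips = 1, gps_noise_sd = 0,
                         sampling_dt = 1, seed = 1)[[1]]
  v <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$t) * 3.6
  expect_equal(v, rep(20.4, length(v)), tolerance = 1e-9)

  truth20 <- speed_table(data.frame(class_kind = "road", class = "trunk",
                                    mean = 20, min = 20, max = 20))
  tr20 <- gen_trajectories(rn, truth20, n_trips = 1, sampling_dt = 1,
                           seed = 1)[[1]]
  expect_equal(nrow(tr20), 181)  # 1000 m at 20 km/h = 180 s, t = 0..180
  expect_equal(tr20$t[181], 180)

  a <- gen_trajectories(rn, truth, n_trips = 3, gps_noise_sd = 4,
                        sampling_dt = 2, seed = 6)
  b <- gen_trajectories(rn, truth, n_trips = 3, gps_noise_sd = 4,
                        sampling_dt = 2, seed = 6)
  expect_identical(a, b)
  expect_error(gen_trajectories(rn, truth, 1, sampling_dt = 0, seed = 1),
               "sampling_dt")
})
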