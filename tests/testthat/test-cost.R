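test_that("stratum selection implements the four-way design", {
  reg <- gen_facilities(grid_spec(15, 15),
                        list(hospital = c(10, 3), health_center = c(69, 6),
                             medical_center = c(3, 45), clinic = c(2, 154)),
                        seed = 5)
  expect_equal(nrow(select_stratum(reg, "all")), 292)
  expect_equal(nrow(select_stratum(reg, "public")), 84)
  expect_equal(nrow(select_stratum(reg, "hospitals")), 13)
  expect_equal(nrow(select_stratum(reg, "public_hospitals")), 10)

  lone <- facility_registry(data.frame(x = 100, y = 100, level = "clinic",
                                       sector = "private", facility_id = 1))
  expect_error(select_stratum(lone, "public"), "no facilities")
})

test_that("1x3 uniform walking grid matches the closed form", {
  sr <- make_speed_surface(matrix(5, 1, 3), walking = TRUE, cell = 30)
  reg <- registry_at_cells(sr$grid, 1, 1)
  tt <- accumulate(sr, NULL, reg)
  expect_equal(tt$values[1, 1], 0)
  expect_equal(tt$values[1, 3], 0.72)  # 60 m at 1.3889 m/s = 43.2 s
})

test_that("accumulation equals the independent graph oracle", {
  skip_if_not_installed("igraph")
  errs <- vapply(1:25, function(s) compare_to_oracle(random_oracle_case(s)),
                 numeric(1))
  expect_lt(max(errs), 1e-9)
})

test_that("uniform friction reproduces octile distance exactly", {
  n <- 21
  sr <- make_speed_surface(matrix(10, n, n), walking = FALSE, cell = 30)
  src <- c(11, 11)
  tt <- accumulate(sr, NULL, registry_at_cells(sr$grid, src[1], src[2]))
  idx <- which(matrix(TRUE, n, n), arr.ind = TRUE)
  want <- octile_distance(idx[, 1], idx[, 2], src[1], src[2], 30) /
    (10 / 3.6) / 60
  expect_equal(as.vector(tt$values), want, tolerance = 1e-12)
})

test_that("barriers are impassable and enclosed cells unreachable", {
  kmh <- matrix(5, 7, 7)
  kmh[3:5, 3] <- 0; kmh[3:5, 5] <- 0; kmh[3, 3:5] <- 0; kmh[5, 3:5] <- 0
  sr <- make_speed_surface(kmh, walking = TRUE, cell = 30)
  tt <- accumulate(sr, NULL, registry_at_cells(sr$grid, 1, 1))
  expect_true(is.na(tt$values[4, 4]))      # inside the ring
  expect_true(all(is.na(tt$values[kmh == 0])))
  expect_false(anyNA(tt$values[1, ]))
})

test_that("facilities on barriers snap within three cells or drop", {
  kmh <- matrix(5, 9, 9)
  kmh[4:6, 4:6] <- 0
  sr <- make_speed_surface(kmh, walking = TRUE, cell = 30)
  reg <- registry_at_cells(sr$grid, 5, 5)   # dead centre of the barrier
  tt <- accumulate(sr, NULL, reg)
  expect_equal(min(tt$values, na.rm = TRUE), 0)  # snapped to passable cell

  big <- matrix(0, 9, 9); big[1, 1] <- 5
  srb <- make_speed_surface(big, walking = TRUE, cell = 30)
  expect_error(
    suppressWarnings(accumulate(srb, NULL, registry_at_cells(srb$grid, 9, 9))),
    "no usable source")
})

test_that("adding facilities never increases travel time anywhere", {
  set.seed(33)
  kmh <- matrix(runif(400, 1, 30), 20, 20)
  sr <- make_speed_surface(kmh, walking = FALSE, cell = 30)
  one <- accumulate(sr, NULL, registry_at_cells(sr$grid, 3, 3))
  two <- accumulate(sr, NULL, registry_at_cells(sr$grid, c(3, 17), c(3, 12)))
  a <- one$values; a[is.na(a)] <- Inf
  b <- two$values; b[is.na(b)] <- Inf
  expect_true(all(b <= a + 1e-12))
})

test_that("anisotropic slope makes uphill slower than downhill walking", {
  sr <- make_speed_surface(matrix(5, 1, 3), walking = TRUE, cell = 30)
  dem <- acc_raster(sr$grid, matrix(c(0, 6, 12), 1, 3))  # 20% grade
  up <- accumulate(sr, dem, registry_at_cells(sr$grid, 1, 1))
  down <- accumulate(sr, dem, registry_at_cells(sr$grid, 1, 3))
  expect_gt(up$values[1, 3], down$values[1, 1])
  # motorized cells ignore slope entirely
  srm <- make_speed_surface(matrix(5, 1, 3), walking = FALSE, cell = 30)
  flat <- accumulate(srm, NULL, registry_at_cells(srm$grid, 1, 1))
  hill <- accumulate(srm, dem, registry_at_cells(srm$grid, 1, 1))
  expect_equal(hill$values, flat$values)
})

test_that("the full design yields one deterministic surface per pair", {
  land <- small_landscape(seed = 50, n = 20)
  tbl <- speed_table(rbind(as.data.frame(reference_road_speeds()),
                           as.data.frame(default_landcover_speeds())))
  rr <- rasterize_roads(land$roads, land$spec, tbl)
  run1 <- run_matrix(rr, land$landcover, land$dem, tbl, land$facilities)
  expect_length(run1, 12)
  expect_named(run1, as.vector(outer(accessim_vocab()$strata,
                                     accessim_vocab()$scenarios,
                                     paste, sep = "|")),
               ignore.order = TRUE)
  run2 <- run_matrix(rr, land$landcover, land$dem, tbl, land$facilities)
  expect_identical(lapply(run1, `[[`, "values"),
                   lapply(run2, `[[`, "values"))
  one <- run_matrix(rr, land$landcover, land$dem, tbl, land$facilities,
                    strata = "all", scenarios = "average")
  expect_length(one, 1)

  # facility-subset and scenario monotonicity on the same design
  inf0 <- function(m) { m[is.na(m)] <- Inf; m }
  for (sc in accessim_vocab()$scenarios) {
    t_all <- inf0(run1[[paste0("all|", sc)]]$values)
    for (st in c("public", "hospitals", "public_hospitals"))
      expect_true(all(t_all <= inf0(run1[[paste(st, sc,
                                                sep = "|")]]$values) + 1e-9))
  }
  for (st in accessim_vocab()$strata) {
    expect_true(all(inf0(run1[[paste0(st, "|maximum")]]$values) <=
                      inf0(run1[[paste0(st, "|average")]]$values) + 1e-9))
    expect_true(all(inf0(run1[[paste0(st, "|average")]]$values) <=
                      inf0(run1[[paste0(st, "|minimum")]]$values) + 1e-9))
  }
})
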