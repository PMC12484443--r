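test_that("nearest-point RWI matching is exact against a scan oracle", {
  g <- grid_spec(5, 5, cell_size = 20)
  tt <- acc_raster(g, matrix(1, 5, 5))
  one <- match_rwi(tt, data.frame(x = 10, y = 10, rwi = 0.7))
  expect_true(all(one$values == 0.7))

  # cell centre at x = 49 sits left of the midpoint of points at 0 and 100
  g1 <- grid_spec(1, 1, cell_size = 98)
  near <- match_rwi(acc_raster(g1, 1),
                    data.frame(x = c(0, 100), y = c(49, 49),
                               rwi = c(-1, 1)))
  expect_equal(near$values[1, 1], -1)

  # tie at exactly half way: lowest point index wins
  g2 <- grid_spec(1, 1, cell_size = 100)
  tie <- match_rwi(acc_raster(g2, 1),
                   data.frame(x = c(0, 100), y = c(50, 50), rwi = c(5, 9)))
  expect_equal(tie$values[1, 1], 5)

  set.seed(8)
  for (rep in 1:5) {
    gg <- grid_spec(sample(5:20, 1), sample(5:20, 1), cell_size = 30)
    pts <- data.frame(x = runif(20, -100, 700), y = runif(20, -100, 700),
                      rwi = rnorm(20))
    got <- match_rwi(acc_raster(gg, 1), pts)
    cc <- cell_centers(gg)
    want <- vapply(seq_len(nrow(cc)), function(i) {
      d <- (cc$x[i] - pts$x)^2 + (cc$y[i] - pts$y)^2
      pts$rwi[which.min(d)]
    }, numeric(1))
    expect_equal(as.vector(got$values), want)
  }
  expect_error(match_rwi(acc_raster(g, 1), data.frame()), "empty")
})

test_that("weighted quintiles follow the cumulative-midpoint rule", {
  a <- assign_quintiles(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(1, 5))
  expect_equal(a$quintile, 1:5)
  # order invariance
  perm <- c(3, 1, 5, 2, 4)
  b <- assign_quintiles(c(0.1, 0.2, 0.3, 0.4, 0.5)[perm], rep(1, 5))
  expect_equal(b$quintile, (1:5)[perm])

  # a dominant first cell spans quintiles: its weight midpoint (40 of 100)
  # lands in quintile 2; the light tail cells all land in quintile 5
  w <- assign_quintiles(1:5, c(80, 5, 5, 5, 5))
  expect_equal(w$quintile, c(2, 5, 5, 5, 5))

  # quintile weight shares balance within one max cell weight of 20%
  set.seed(3)
  v <- runif(200); wt <- runif(200, 0, 4)
  q <- assign_quintiles(v, wt)
  shares <- tapply(wt, q$quintile, sum) / sum(wt)
  expect_true(all(abs(shares - 0.2) <= max(wt) / sum(wt) + 1e-12))
  expect_true(all(diff(q$quintile[order(v)]) >= 0))

  expect_error(assign_quintiles(1:3, c(0, 0, 0)), "positive")
})

test_that("equiplot means are weighted, zone-restricted and consistent", {
  g <- grid_spec(5, 5, cell_size = 30)
  zs <- zone_set(list(list(
    ring = cbind(c(0, 150, 150, 0), c(0, 0, 150, 150)),
    zone_id = "study", zone_level = "study_area")))
  pop <- acc_raster(g, matrix(runif(25, 1, 3), 5, 5))
  rwi <- acc_raster(g, matrix(seq(0, 1, length.out = 25), 5, 5))
  asg <- assign_quintiles(rwi$values, pop$values)

  uni <- equiplot_table(acc_raster(g, matrix(10, 5, 5)), asg, zs)
  expect_equal(uni$mean_tt, rep(10, 5))
  expect_equal(nrow(uni), 5)

  tt <- acc_raster(g, matrix(runif(25, 5, 60), 5, 5))
  eq <- equiplot_table(tt, asg, zs)
  # per-quintile sums recombine to the global weighted mean
  global <- sum(tt$values * pop$values) / sum(pop$values)
  expect_equal(sum(eq$mean_tt * eq$wocba) / sum(eq$wocba), global,
               tolerance = 1e-12)
  # brute-force check of each quintile's weighted mean
  for (q in 1:5) {
    cells <- which(asg$quintile == q)
    expect_equal(eq$mean_tt[eq$quintile == q],
                 sum(tt$values[cells] * pop$values[cells]) /
                   sum(pop$values[cells]))
  }
})

test_that("a pro-rich landscape yields the expected equiplot gap", {
  # poorest fifth of cells at 50 minutes, richest at 10: gap ratio 5
  g <- grid_spec(5, 5, cell_size = 30)
  rwi_vals <- matrix(rep(1:5, each = 5), 5, 5)       # five wealth bands
  tt <- acc_raster(g, matrix(rep(c(50, 40, 30, 20, 10), each = 5), 5, 5))
  pop <- acc_raster(g, matrix(1, 5, 5))
  asg <- assign_quintiles(rwi_vals, pop$values)
  zs <- zone_set(list(list(
    ring = cbind(c(0, 150, 150, 0), c(0, 0, 150, 150)),
    zone_id = "study", zone_level = "study_area")))
  eq <- equiplot_table(tt, asg, zs)
  expect_equal(eq$mean_tt, c(50, 40, 30, 20, 10))
  expect_equal(eq$mean_tt[eq$quintile == 1] / eq$mean_tt[eq$quintile == 5], 5)
})

test_that("facility placement independent of wealth flattens the gap", {
  # with facilities everywhere and RWI spatially independent of access,
  # quintile means concentrate around the global mean
  set.seed(91)
  g <- grid_spec(30, 30, cell_size = 30)
  tt <- acc_raster(g, matrix(sample(rep(seq(2, 20, length.out = 900))),
                             30, 30))
  rwi <- acc_raster(g, matrix(sample(rep(seq(-1, 1, length.out = 900))),
                              30, 30))
  pop <- acc_raster(g, matrix(1, 30, 30))
  asg <- assign_quintiles(rwi$values, pop$values)
  zs <- zone_set(list(list(
    ring = cbind(c(0, 900, 900, 0), c(0, 0, 900, 900)),
    zone_id = "study", zone_level = "study_area")))
  eq <- equiplot_table(tt, asg, zs)
  expect_lt(max(eq$mean_tt) - min(eq$mean_tt),
            0.2 * mean(tt$values))
})

test_that("urbanicity summaries are population-weighted band means", {
  g <- grid_spec(2, 2, cell_size = 30)
  tt <- acc_raster(g, matrix(c(10, 10, 50, 50), 2, 2))
  urb <- acc_raster(g, matrix(c(2, 2, 1, 1), 2, 2))
  attr(urb, "bands") <- c("village", "city")
  pop <- acc_raster(g, matrix(1, 2, 2))
  us <- urbanicity_summary(tt, urb, pop)
  expect_equal(us$mean_tt[us$band_name == "city"], 10)
  expect_equal(us$mean_tt[us$band_name == "village"], 50)
  expect_lt(us$mean_tt[us$band_name == "city"],
            us$mean_tt[us$band_name == "village"])

  one <- urbanicity_summary(tt, acc_raster(g, matrix(1, 2, 2)), pop)
  expect_equal(one$mean_tt, mean(tt$values))
  expect_equal(nrow(one), 1)
})
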