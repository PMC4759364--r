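test_that("raw autocorrelation reproduces hand-computed values", {
  const <- rep(2, 10)
  acf1 <- autocorrelation(const, max_lag = 5, variant = "raw")
  expect_equal(acf1$values, rep(4, 6))

  alt <- c(1, -1, 1, -1)
  acf2 <- autocorrelation(alt, max_lag = 2, variant = "raw")
  expect_equal(acf2$values[1], 1)    # lag 0: mean square
  expect_equal(acf2$values[2], -1)   # lag 1: hand evaluation
  expect_equal(acf2$values[3], 1)

  set.seed(2)
  x <- rnorm(50)
  expect_equal(autocorrelation(x, 0, "raw")$values[1], mean(x^2))
  expect_error(autocorrelation(x, 50), "max_lag")
})

test_that("normalized autocorrelation starts at 1 and tracks AR(1) decay", {
  set.seed(5)
  x <- ar1_series(20000, 0.8)
  acf <- autocorrelation(x, max_lag = 10, variant = "normalized")
  expect_equal(acf$values[1], 1)
  # loose check here; the tight 3-SE check runs at full scale elsewhere
  expect_equal(acf$values[2], 0.8, tolerance = 0.05)
  expect_equal(acf$values[6], 0.8^5, tolerance = 0.1)
})

test_that("free-energy map is zero for uniform occupancy and at the minimum", {
  # one sample exactly in each bin of a 5 x 4 grid
  g <- expand.grid(x = seq(0.05, 0.45, by = 0.1),
                   y = seq(0.05, 0.35, by = 0.1))
  fel <- free_energy_map(g$x, g$y, temperature = 300, bins = 5)
  expect_true(all(abs(fel$delta_g[!is.na(fel$delta_g)]) < 1e-12))

  set.seed(8)
  fel2 <- free_energy_map(rnorm(500, 0.5, 0.1), rnorm(500, 0.8, 0.1),
                          temperature = 300)
  expect_equal(min(fel2$delta_g, na.rm = TRUE), 0)
  expect_equal(sum(fel2$counts), 500)
  expect_true(all(is.na(fel2$delta_g[fel2$counts == 0])))
})

test_that("two-bin occupancy ratio e gives dG = kB T", {
  n1 <- 27183L; n2 <- 10000L  # ratio ~ e
  x <- c(rep(0.25, n1), rep(0.75, n2))
  y <- rep(0.5, n1 + n2)
  fel <- free_energy_map(x, y, temperature = 300, bins = 2)
  dg <- fel$delta_g[!is.na(fel$delta_g)]
  expect_equal(max(dg), 0.0083145 * 300 * log(n1 / n2), tolerance = 1e-9)
  expect_equal(max(dg), 2.494, tolerance = 0.001)
})

test_that("maps are permutation-invariant and contract when counts are padded", {
  set.seed(13)
  x <- rnorm(2000, 0.4, 0.08); y <- rnorm(2000, 0.8, 0.05)
  fel <- free_energy_map(x, y, temperature = 300, bins = 8)
  ord <- sample(length(x))
  fel_p <- free_energy_map(x[ord], y[ord], temperature = 300, bins = 8)
  expect_equal(fel$delta_g, fel_p$delta_g)
  expect_equal(fel$counts, fel_p$counts)

  # adding a constant count to every bin shrinks the dG spread
  xc <- (fel$x_edges[-1] + fel$x_edges[-9]) / 2
  yc <- (fel$y_edges[-1] + fel$y_edges[-9]) / 2
  pad <- expand.grid(x = xc, y = yc)
  pad <- pad[rep(seq_len(nrow(pad)), 3), ]
  fel_c <- free_energy_map(c(x, pad$x), c(y, pad$y), temperature = 300,
                           bins = 8)
  expect_lt(max(fel_c$delta_g, na.rm = TRUE),
            max(fel$delta_g, na.rm = TRUE))
})

test_that("basin extraction returns the connected region of the global minimum", {
  # single occupied bin
  fel1 <- free_energy_map(rep(0.5, 10), rep(0.5, 10), bins = 3)
  b1 <- basin_extract(fel1, 1.5)
  expect_equal(nrow(b1$member_bins), 1L)
  expect_equal(b1$occupancy, 1)

  # two wells separated by an empty ridge: only the minimum's well
  set.seed(21)
  x <- c(rnorm(3000, 0.3, 0.02), rnorm(1000, 0.9, 0.02))
  y <- c(rnorm(3000, 0.5, 0.02), rnorm(1000, 0.5, 0.02))
  fel2 <- free_energy_map(x, y, temperature = 300)
  b2 <- basin_extract(fel2, 1.5)
  expect_lt(b2$rmsd_range[2], 0.6)  # stays in the left well
  expect_gte(b2$occupancy, 0.25)
  # a higher threshold widens the basin but still cannot cross the ridge
  b3 <- basin_extract(fel2, 2.5)
  expect_lt(b3$rmsd_range[2], 0.6)
  expect_gte(b3$occupancy, b2$occupancy)

  # infinite threshold: all defined bins of the connected component
  b_inf <- basin_extract(fel1, Inf)
  expect_equal(nrow(b_inf$member_bins), sum(fel1$counts > 0))
})

test_that("local minima enumeration finds separated wells", {
  set.seed(22)
  x <- c(rnorm(3000, 0.3, 0.02), rnorm(3000, 0.9, 0.02))
  y <- c(rnorm(3000, 0.5, 0.02), rnorm(3000, 0.5, 0.02))
  fel <- free_energy_map(x, y, temperature = 300)
  basins <- local_minima(fel, 1.5)
  expect_equal(length(basins), 2L)
  expect_equal(basins[[1]]$min_delta_g, 0)
  expect_gt(basins[[2]]$min_delta_g, 0)
  # negative threshold excludes everything (dG >= 0)
  expect_equal(length(local_minima(fel, -1)), 0L)
  # a uniform map is one basin
  g <- expand.grid(x = 1:4 / 10, y = 1:4 / 10)
  expect_equal(length(local_minima(free_energy_map(g$x, g$y, bins = 4), 1)),
               1L)
})

test_that("trajectory overlay reports visitation and basin occupancy", {
  set.seed(23)
  x <- rnorm(1000, 0.4, 0.05); y <- rnorm(1000, 0.8, 0.05)
  fel <- free_energy_map(x, y, temperature = 300)
  ov <- overlay_trajectory(fel, x, y)
  expect_equal(ov$occupancy, 1)
  expect_equal(ov$n_out_of_range, 0L)
  # visited bins are a subset of occupied bins
  expect_true(all(fel$counts[ov$visited] > 0))

  far <- overlay_trajectory(fel, x + 100, y)
  expect_equal(far$occupancy, 0)
  expect_equal(far$n_out_of_range, 1000L)

  bas <- basin_extract(fel, 2.5)
  ovb <- overlay_trajectory(fel, x, y, basin = bas)
  expect_equal(ovb$occupancy, bas$occupancy, tolerance = 1e-12)
})

test_that("fel_table exports bin centers with counts and dG", {
  fel <- free_energy_map(runif(50), runif(50), bins = 4)
  tab <- fel_table(fel)
  expect_equal(nrow(tab), 16L)
  expect_equal(sum(tab$count), 50)
  expect_named(tab, c("rmsd_nm", "rg_nm", "count", "delta_g_kjmol"))
})
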