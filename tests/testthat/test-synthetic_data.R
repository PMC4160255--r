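test_that("the generator is bit-identical under a fixed seed", {
  a <- make_benchmark_dataset(seed = 1)
  b <- make_benchmark_dataset(seed = 1)
  expect_identical(a$measurements, b$measurements)
  expect_identical(as.data.frame(a$climate$tmax), as.data.frame(b$climate$tmax))
  expect_identical(a$truth, b$truth)
  c_ <- make_benchmark_dataset(seed = 2)
  expect_false(identical(a$measurements, c_$measurements))
})

test_that("config validation enforces the sign structure and stationarity", {
  expect_error(generator_config(gamma_t = -0.1), "sign structure")
  expect_error(generator_config(gamma_p = 0.1), "sign structure")
  expect_error(generator_config(gamma_t = 0.4, gamma_p = -0.2), "negative")
  expect_error(generator_config(ar1 = 1.2), "stationarity")
})

test_that("zero anomaly spread reproduces the seasonal climatology exactly", {
  cfg <- generator_config(seed = 1, tmax_sd = 0, tmean_sd = 0,
                          precip_log_sd = 0)
  clim <- simulate_climate(cfg)
  expect_true(all(abs(t(as.matrix(as.data.frame(clim$tmax)[, -1])) -
                        cfg$tmax_mean) < 1e-12))
  expect_equal(unname(rowSums(as.data.frame(clim$precip)[, -1])),
               rep(521.0, nrow(clim$precip)), tolerance = 1e-9)
})

test_that("the configured climatology carries the site's seasonal structure", {
  cfg <- generator_config()
  expect_equal(mean(cfg$tmean_mean), 11.0, tolerance = 1e-9)   # annual mean temperature
  expect_equal(sum(cfg$precip_mean), 521.0, tolerance = 1e-9)  # annual precipitation
  expect_equal(sum(cfg$precip_mean[6:9]) / sum(cfg$precip_mean), 0.648,
               tolerance = 5e-4)                               # monsoon-season share
  expect_equal(which.max(cfg$tmean_mean), 7L)                  # July warmest
  expect_equal(which.min(cfg$precip_mean), 12L)                # December driest
  expect_equal(mean(cfg$tmax_mean[5:6]), 25.6, tolerance = 1e-9)
})

test_that("long-run simulated climate converges to the configured means", {
  cfg <- generator_config(seed = 2, climate_span = c(1L, 4000L),
                          span = c(1L, 4000L))
  clim <- simulate_climate(cfg)
  ann_t <- rowMeans(as.data.frame(clim$tmean)[, -1])
  expect_equal(mean(ann_t), 11.0, tolerance = 0.1)
  ann_p <- rowSums(as.data.frame(clim$precip)[, -1])
  expect_equal(mean(ann_p), 521.0, tolerance = 0.02 * 521)
  expect_true(all(as.matrix(as.data.frame(clim$precip)[, -1]) >= 0))
})

test_that("the no-signal no-noise limit returns cores exactly on their growth curves", {
  cfg <- generator_config(seed = 3, gamma_t = 1e-9, gamma_p = -1e-9,
                          sigma_site = 0, sigma_tree = 0, sigma_core = 0)
  clim <- simulate_climate(cfg)
  cores <- simulate_cores(cfg, clim)
  s <- cores$measurements[[1]]
  pars <- cores$truth$curves[[s$tree_id]]
  t <- seq_along(s$values) - 1
  expect_equal(s$values, unname(pars["a"] * exp(-pars["b"] * t) + pars["d"]),
               tolerance = 1e-6)
  idx <- detrend_series(s)
  expect_true(all(abs(idx$indices - 1) < 1e-3))
})

test_that("the depth schedule keeps 4 trees / 6 cores at the first year and full depth later", {
  bm <- make_benchmark_dataset(seed = 4)
  expect_length(bm$measurements, 63L)
  firsts <- vapply(bm$measurements, function(s) s$first_year, integer(1))
  trees <- vapply(bm$measurements, function(s) s$tree_id, character(1))
  at_start <- firsts <= 1666L
  expect_gte(length(unique(trees[at_start])), 4L)
  expect_gte(sum(at_start), 6L)
  expect_equal(length(unique(trees)), 25L)
  expect_true(all(firsts <= 1900L))
  expect_true(all(vapply(bm$measurements,
                         function(s) all(s$values >= 0), logical(1))))
})

test_that("stronger temperature coupling raises the chronology-temperature correlation", {
  gammas <- c(0.02, 0.04, 0.08)
  mean_r <- vapply(gammas, function(g) {
    rs <- vapply(1:20, function(s) {
      cfg <- generator_config(seed = s, gamma_t = g)
      clim <- simulate_climate(cfg)
      cores <- simulate_cores(cfg, clim)
      cores$truth$true_r
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("the benchmark calibration-window signal sits at the designed strength", {
  rs <- vapply(1:25, function(s) {
    bm <- make_benchmark_dataset(seed = s)
    ch <- truncate_reliable(build_chronology(detrend(bm$measurements)))
    cal <- bm$truth$calibration_years
    stats::cor(ch$index[match(cal, ch$year)],
               unname(bm$truth$tmax_mj[as.character(cal)]))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.63), 0.1)
})

test_that("the fixture directory is written complete and reloadable", {
  dir <- withr::local_tempdir()
  bm <- make_benchmark_dataset(seed = 6, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("measurements.csv", "tmax.csv",
                                               "tmean.csv", "precip.csv",
                                               "truth.json", "README")))))
  meas <- read_measurement_csv(file.path(dir, "measurements.csv"))
  expect_length(meas, 63L)
  expect_equal(meas[[1]]$values, bm$measurements[[1]]$values, tolerance = 1e-12)
  tm <- read_climate_csv(file.path(dir, "tmax.csv"), "tmax")
  expect_equal(range(tm$year), c(1951L, 2008L))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$true_beta1, bm$truth$true_beta1, tolerance = 1e-9)
})
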