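make_climate <- function(years, fill = NULL, seed = 1) {
  set.seed(seed)
  vals <- if (is.null(fill)) matrix(15 + stats::rnorm(length(years) * 12), ncol = 12)
  else matrix(fill, nrow = length(years), ncol = 12, byrow = TRUE)
  df <- data.frame(year = years, vals)
  names(df) <- c("year", paste0("m", 1:12))
  climate_table(df, "tmax")
}

test_that("the default monthly window runs prior July through current September", {
  w <- month_window()
  expect_equal(nrow(w), 15L)
  expect_equal(w$rel_year[1], "prior"); expect_equal(w$month[1], 7L)
  expect_equal(w$rel_year[15], "current"); expect_equal(w$month[15], 9L)
  expect_true(all(diff(ifelse(w$rel_year == "prior", -12, 0) + w$month) == 1L))
})

test_that("build_month_matrix looks up current and prior-year slots correctly", {
  clim <- make_climate(1950:1960)
  w <- month_window(c("current", 5), c("current", 6))
  M <- build_month_matrix(clim, w, 1954:1955)
  expect_equal(dim(M), c(2L, 2L))
  expect_equal(M["1954", "curr_may"], clim$m5[clim$year == 1954])
  expect_equal(M["1955", "curr_jun"], clim$m6[clim$year == 1955])

  wp <- month_window(c("prior", 7), c("current", 2))
  Mp <- build_month_matrix(clim, wp, 1954)
  expect_equal(Mp["1954", "prio_jul"], clim$m7[clim$year == 1953])

  expect_error(build_month_matrix(clim, wp, 1950), "alignment")
})

test_that("seasonal_mean averages the requested months per year", {
  clim <- make_climate(1953:2008)
  mj <- seasonal_mean(clim, 5:6)
  expect_length(mj, 56L)
  expect_equal(unname(mj[1]), mean(c(clim$m5[1], clim$m6[1])))
})

test_that("bootstrap correlation flags a copied predictor as perfectly significant", {
  clim <- make_climate(1950:2009)
  w <- month_window(c("current", 1), c("current", 12))
  M <- build_month_matrix(clim, w, 1953:2008)
  idx <- M[, "curr_may"]
  res <- bootstrap_correlations(idx, M, n_boot = 500, seed = 1)
  may <- res[res$slot == "curr_may", ]
  expect_equal(may$coefficient, 1.0)
  expect_true(may$significant)
  expect_true(all(abs(res$coefficient) <= 1))
  expect_true(all(res$significant == (res$lower > 0 | res$upper < 0)))
})

test_that("bootstrap correlations are deterministic given the seed and stable in n_boot", {
  set.seed(14)
  idx <- stats::rnorm(56)
  M <- matrix(stats::rnorm(56 * 5), 56, 5, dimnames = list(NULL, paste0("s", 1:5)))
  r1 <- bootstrap_correlations(idx, M, n_boot = 1000, seed = 99)
  r2 <- bootstrap_correlations(idx, M, n_boot = 1000, seed = 99)
  expect_identical(r1, r2)
  # bounds converge as n_boot grows: two large runs, different seeds
  b1 <- bootstrap_correlations(idx, M, n_boot = 10000, seed = 1)
  b2 <- bootstrap_correlations(idx, M, n_boot = 10000, seed = 2)
  expect_lt(max(abs(b1$lower - b2$lower)), 0.01)
  expect_lt(max(abs(b1$upper - b2$upper)), 0.01)
})

test_that("zero-variance slots are flagged undefined, others still computed", {
  set.seed(15)
  idx <- stats::rnorm(56)
  M <- cbind(flat = rep(3, 56),
             ok = stats::rnorm(56))
  res <- bootstrap_correlations(idx, M, n_boot = 500, seed = 3)
  expect_equal(res$flag, c("undefined", "ok"))
  expect_true(is.na(res$coefficient[1]))
  expect_false(is.na(res$coefficient[2]))
})

test_that("response function recovers a planted single-month signal", {
  set.seed(16)
  n <- 200
  M <- matrix(stats::rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("s", 1:6)))
  y <- 0.8 * M[, 1] + stats::rnorm(n, 0, 0.3)
  res <- response_function(y, M, n_boot = 500, seed = 5)
  expect_true(res$significant[1])
  expect_gt(res$coefficient[1], 0)
  expect_false(any(res$significant[-1]))
})

test_that("response coefficients are symmetric under duplicated predictors and affine rescaling", {
  set.seed(17)
  n <- 80
  base <- matrix(stats::rnorm(n * 3), n, 3)
  M <- cbind(a = base[, 1], b = base[, 2], adup = base[, 1], c = base[, 3])
  y <- 0.5 * base[, 1] + stats::rnorm(n, 0, 0.5)
  res <- response_function(y, M, n_boot = 500, seed = 6)
  expect_equal(res$coefficient[res$slot == "a"],
               res$coefficient[res$slot == "adup"], tolerance = 1e-9)
  # affine rescaling of a column leaves standardized coefficients unchanged
  M2 <- M; M2[, "c"] <- 100 + 7 * M2[, "c"]
  res2 <- response_function(y, M2, n_boot = 500, seed = 6)
  expect_equal(res$coefficient, res2$coefficient, tolerance = 1e-9)
})

test_that("null response functions stay mostly non-significant", {
  set.seed(18)
  clean <- 0L
  for (k in 1:30) {
    M <- matrix(stats::rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("s", 1:5)))
    y <- stats::rnorm(60)
    res <- response_function(y, M, n_boot = 500, seed = k)
    if (!any(res$significant)) clean <- clean + 1L
  }
  expect_gte(clean, 30 * 0.6)   # >= 90% of slots clean implies most runs fully clean
})

test_that("partial correlation matches the residual-correlation brute force", {
  x <- 1:12; y <- rev(x); z <- rep(c(1, -1), 6)
  pc <- partial_correlation(x, y, z)
  brute <- stats::cor(stats::residuals(stats::lm(x ~ z)),
                      stats::residuals(stats::lm(y ~ z)))
  expect_equal(pc$estimate, brute, tolerance = 1e-12)

  set.seed(19)
  for (k in 1:20) {
    a <- stats::rnorm(30); b <- stats::rnorm(30); c <- stats::rnorm(30)
    pc <- partial_correlation(a, b, c)
    brute <- stats::cor(stats::residuals(stats::lm(a ~ c)),
                        stats::residuals(stats::lm(b ~ c)))
    expect_equal(pc$estimate, brute, tolerance = 1e-12)
  }
})

test_that("partial correlation limits and degeneracies behave", {
  set.seed(20)
  n <- 2000
  x <- stats::rnorm(n); y <- 0.6 * x + stats::rnorm(n, 0, 0.8); z <- stats::rnorm(n)
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$estimate, stats::cor(x, y), tolerance = 0.05)
  expect_error(partial_correlation(x, y, x), "degenerate")
})

test_that("benchmark chronology shows the expected monthly sign pattern", {
  bm <- make_benchmark_dataset(seed = 30)
  ch <- truncate_reliable(build_chronology(detrend(bm$measurements)))
  yrs <- 1953:2008
  idx <- ch$index[match(yrs, ch$year)]
  w <- month_window(c("current", 5), c("current", 6))
  Mt <- build_month_matrix(bm$climate$tmax, w, yrs)
  Mp <- build_month_matrix(bm$climate$precip, w, yrs)
  colnames(Mp) <- paste0("p_", colnames(Mp))
  res <- bootstrap_correlations(idx, cbind(Mt, Mp), n_boot = 500, seed = 1)
  expect_gt(res$coefficient[res$slot == "curr_may"], 0)
  expect_true(res$significant[res$slot == "curr_may"] ||
                res$significant[res$slot == "curr_jun"])
  expect_lt(res$coefficient[res$slot == "p_curr_may"], 0)
})
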