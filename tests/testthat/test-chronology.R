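test_that("biweight mean matches trivial and oracle cases", {
  expect_equal(biweight_mean(rep(3.7, 5)), 3.7)
  expect_equal(biweight_mean(c(1, 2, 3)), 2)
  expect_error(biweight_mean(numeric(0)), "empty")

  v <- c(1.0, 1.1, 0.9, 1.0, 10.0)
  m <- biweight_mean(v)
  expect_gt(m, 0.9); expect_lt(m, 1.2)
  expect_lt(abs(m - 1.0), abs(mean(v) - 1.0))      # outlier resistance
  expect_equal(m, bw_oracle(v), tolerance = 1e-8)  # independent fixed-point loop

  set.seed(5)
  for (k in 1:20) {
    x <- stats::rnorm(sample(3:40, 1)) + sample(c(0, 8), 1) * stats::rbinom(1, 1, 0.3)
    expect_equal(biweight_mean(x), bw_oracle(x), tolerance = 1e-7)
  }
})

test_that("biweight mean is scale equivariant and matches the mean for clean data", {
  set.seed(6)
  x <- stats::rnorm(50, 10, 0.01)    # tight symmetric cloud: everything inside |u|<1
  expect_equal(biweight_mean(x), mean(x), tolerance = 1e-4)
  expect_equal(biweight_mean(3.5 * x), 3.5 * biweight_mean(x), tolerance = 1e-9)
})

test_that("EPS formula reproduces closed-form anchors and is monotone", {
  expect_equal(eps_formula(6, 0.4), 0.8)
  expect_equal(eps_formula(7, 0.315), 0.763, tolerance = 5e-4)
  expect_equal(eps_formula(2, 1), 1)
  expect_equal(eps_formula(10, -0.2), 0)
  # strictly increasing in n and in rbar
  ns <- 2:30; rbars <- seq(0.05, 0.95, by = 0.05)
  for (r in rbars) expect_true(all(diff(eps_formula(ns, r)) > 0))
  for (n in ns) expect_true(all(diff(eps_formula(n, rbars)) > 0))
})

test_that("two identical series give a perfect chronology", {
  set.seed(8)
  vals <- 1 + stats::rnorm(120, 0, 0.1)
  idx <- list(make_index_series("A1", "A", 1850, vals),
              make_index_series("A2", "A", 1850, vals))
  ch <- build_chronology(idx)
  expect_equal(ch$index, vals, tolerance = 1e-9)
  win <- attr(ch, "windows")
  expect_true(all(abs(win$rbar - 1) < 1e-12))
  expect_true(all(abs(win$eps - 1) < 1e-12))
})

test_that("independent white-noise series give near-zero rbar", {
  set.seed(9)
  idx <- lapply(1:6, function(i) noise_index_series(paste0("N", i), paste0("t", i),
                                                    1700, 300))
  win <- running_rbar_eps(idx, window = 300L, overlap = 150L)
  full <- win[win$end - win$start + 1L == 300L, ][1, ]
  expect_lt(abs(full$rbar), 0.1)   # 95% sampling bound for mean pairwise cor, n=300
})

test_that("windows with rbar <= 0 report EPS 0 with a flag, < 2 series undefined", {
  set.seed(10)
  a <- stats::rnorm(40)
  idx <- list(make_index_series("A", "a", 1900, 1 + 0.1 * a),
              make_index_series("B", "b", 1900, 1 - 0.1 * a))
  win <- running_rbar_eps(idx, window = 40L, overlap = 20L)
  expect_true(all(win$eps[win$rbar <= 0] == 0))
  expect_true(all(win$flag[win$rbar <= 0] == "low_signal"))

  lone <- list(make_index_series("A", "a", 1900, 1 + 0.1 * a),
               make_index_series("B", "b", 2000, rep(1, 40)))
  win2 <- suppressWarnings(running_rbar_eps(lone, window = 40L, overlap = 20L))
  expect_true(any(win2$flag == "undefined"))
})

test_that("coverage gaps inside the union span are rejected", {
  idx <- list(make_index_series("A", "a", 1900, rep(1, 10)),
              make_index_series("B", "b", 1920, rep(1, 10)))
  expect_error(build_chronology(idx), "coverage-gap")
})

test_that("benchmark chronology recovers the imposed common-variance fraction", {
  bm <- make_benchmark_dataset(seed = 21)
  idx <- detrend(bm$measurements)
  im_years <- range(vapply(idx, function(s) s$first_year, integer(1)))
  win <- running_rbar_eps(idx, window = 343L, overlap = 0L)
  full <- win[1, ]
  expect_lt(abs(full$rbar - bm$truth$rbar_pop), 0.05)
})

test_that("reliability truncation honours depth and the EPS override", {
  # depth drops below 4 trees before a known year: generator schedule oracle
  cfg <- generator_config(seed = 3, start_years = c(rep(1666L, 3L),
                                                    rep(1750L, 22L)))
  bm <- make_benchmark_dataset(config = cfg)
  ch <- build_chronology(detrend(bm$measurements))
  expect_equal(attr(ch, "reliable_from"), 1750L)
  tr <- truncate_reliable(ch)
  expect_equal(tr$year[1], 1750L)
  expect_true(all(tr$n_trees >= 4 & tr$n_cores >= 6))

  # chronology healthy throughout stays untouched
  bm2 <- make_benchmark_dataset(seed = 4)
  ch2 <- build_chronology(detrend(bm2$measurements))
  tr2 <- truncate_reliable(ch2)
  expect_equal(nrow(tr2), nrow(ch2))

  # no qualifying year -> empty-reliable-period error
  ch3 <- build_chronology(detrend(bm2$measurements), eps_threshold = 0.999,
                          eps_override = 0.999)
  expect_error(truncate_reliable(ch3), "empty-reliable-period")
})

test_that("EPS override retains a low-EPS window when tree depth is adequate", {
  # interior window at EPS ~0.76 with >= 4 trees: retained under the override
  set.seed(33)
  n <- 90
  common <- stats::rnorm(n)
  # weaken the common signal in the middle third only
  weight <- rep(1, n); weight[31:60] <- 0.45
  idx <- lapply(1:7, function(i) {
    tree <- paste0("t", ((i - 1) %% 4) + 1)
    make_index_series(paste0("S", i), tree, 1800,
                      1 + 0.1 * (weight * common + stats::rnorm(n, 0, 0.45)))
  })
  ch <- build_chronology(idx, window = 30L, overlap = 15L)
  win <- attr(ch, "windows")
  mid <- win$eps[win$start == 1830]
  # with the override an interior dip above 0.75 does not truncate
  if (!is.na(mid) && mid >= 0.75 && mid <= 0.8) {
    expect_equal(attr(ch, "reliable_from"), 1800L)
  }
  expect_true(all(!is.na(win$eps)))
})

test_that("n_trees never exceeds n_cores and chronology spans are contiguous", {
  bm <- make_benchmark_dataset(seed = 5)
  ch <- build_chronology(detrend(bm$measurements))
  expect_true(all(ch$n_trees <= ch$n_cores))
  expect_true(all(diff(ch$year) == 1L))
  expect_true(all(ch$eps >= 0 & ch$eps <= 1, na.rm = TRUE))
  expect_true(all(abs(ch$rbar) <= 1, na.rm = TRUE))
})
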