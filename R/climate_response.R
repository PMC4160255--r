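#' Define an ordered monthly climate window
#'
#' A window is an ordered list of (relative year, month) slots spanning the
#' biological year, e.g. the classic dendroclimatic window from July of the
#' year before growth to September of the growth year (15 slots). Slots in
#' the prior year are tagged `"prior"`, growth-year slots `"current"`.
#'
#' @param start,end Length-2 vectors `c(rel_year, month)` with `rel_year`
#'   `"prior"` or `"current"` and month 1-12.
#' @return A data frame of class `month_window` with columns `rel_year`,
#'   `month`, `label`.
#' @export
month_window <- function(start = c("prior", 7), end = c("current", 9)) {
  rel <- c(prior = -1L, current = 0L)
  s <- rel[[start[1]]] * 12L + as.integer(start[2])
  e <- rel[[end[1]]] * 12L + as.integer(end[2])
  if (e < s) stop("month_window: end precedes start", call. = FALSE)
  lin <- seq.int(s, e)
  if (length(lin) > 24L) stop("month_window: window longer than 24 months", call. = FALSE)
  rel_year <- ifelse(lin <= 0L, "prior", "current")
  month <- ifelse(lin <= 0L, lin + 12L, lin)
  w <- data.frame(rel_year = rel_year, month = as.integer(month))
  w$label <- paste0(substr(w$rel_year, 1, 4), "_", tolower(month.abb[w$month]))
  structure(w, class = c("month_window", "data.frame"))
}

#' Build the monthly predictor matrix for a set of growth years
#'
#' One row per target growth year, one column per window slot; prior-year
#' slots take their values from the preceding calendar year.
#'
#' @param climate A `climate_table`.
#' @param window A [month_window()].
#' @param years Target growth years.
#' @return Numeric matrix `length(years) x nrow(window)` with slot labels
#'   as column names and years as row names.
#' @export
build_month_matrix <- function(climate, window, years) {
  need_prior <- any(window$rel_year == "prior")
  avail <- climate$year
  need <- if (need_prior) c(min(years) - 1L, years) else years
  missing_years <- setdiff(need, avail)
  if (length(missing_years) > 0L) {
    stop("build_month_matrix: alignment error, climate lacks year(s) ",
         paste(sort(missing_years), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(climate[, paste0("m", 1:12)])
  rownames(vals) <- climate$year
  out <- matrix(NA_real_, nrow = length(years), ncol = nrow(window),
                dimnames = list(years, window$label))
  for (j in seq_len(nrow(window))) {
    src <- if (window$rel_year[j] == "prior") years - 1L else years
    out[, j] <- vals[as.character(src), window$month[j]]
  }
  out
}

#' Seasonal mean of current-year months
#'
#' Convenience helper for transfer-function targets, e.g. the May-June
#' maximum-temperature mean.
#'
#' @param climate A `climate_table`.
#' @param months Month numbers to average (default `5:6`).
#' @param years Target years (default all years in the table).
#' @return Named numeric vector (names = years).
#' @export
seasonal_mean <- function(climate, months = 5:6, years = climate$year) {
  if (!all(years %in% climate$year)) {
    stop("seasonal_mean: requested years outside the climate record", call. = FALSE)
  }
  vals <- as.matrix(climate[match(years, climate$year), paste0("m", months),
                            drop = FALSE])
  out <- rowMeans(vals)
  names(out) <- years
  out
}

#' Bootstrapped correlation function
#'
#' Pearson correlation of the chronology index with each monthly slot,
#' with percentile confidence bounds from paired-year resampling: whole
#' years are drawn with replacement, keeping index and all predictor slots
#' together. A slot is flagged significant when its bootstrap interval
#' excludes zero. Zero-variance slots are flagged undefined and skipped.
#'
#' @param chron_index Annual index values (vector).
#' @param predictors Matrix from [build_month_matrix()], rows matching
#'   `chron_index`.
#' @param n_boot Number of bootstrap resamples (>= 500, default 1000).
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param level Confidence level (default 0.95).
#' @return A data frame of class `response_result`: `slot`, `coefficient`,
#'   `lower`, `upper`, `significant`, `p` (t-transform p-value), `flag`.
#' @export
bootstrap_correlations <- function(chron_index, predictors, n_boot = 1000L,
                                   seed, level = 0.95) {
  n <- length(chron_index)
  stopifnot(nrow(predictors) == n)
  if (n < 30L) stop("bootstrap_correlations: need >= 30 common years", call. = FALSE)
  if (n_boot < 500L) stop("bootstrap_correlations: n_boot must be >= 500", call. = FALSE)
  sds <- apply(predictors, 2L, stats::sd)
  defined <- is.finite(sds) & sds > 0 & stats::sd(chron_index) > 0
  r <- rep(NA_real_, ncol(predictors))
  r[defined] <- as.vector(stats::cor(chron_index, predictors[, defined, drop = FALSE]))
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, nrow = n_boot, ncol = ncol(predictors))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, defined] <- suppressWarnings(
      as.vector(stats::cor(chron_index[idx], predictors[idx, defined, drop = FALSE])))
  }
  alpha <- (1 - level) / 2
  lo <- apply(boot, 2L, stats::quantile, probs = alpha, na.rm = TRUE)
  hi <- apply(boot, 2L, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(
    data.frame(slot = colnames(predictors), coefficient = r,
               lower = lo, upper = hi,
               significant = defined & (lo > 0 | hi < 0),
               p = p,
               flag = ifelse(defined, "ok", "undefined"),
               row.names = NULL),
    class = c("response_result", "data.frame"),
    kind = "correlation", n = n, n_boot = n_boot, seed = seed)
}

# one PC-regression pass: standardized predictors -> month-space coefficients
pc_regression_coef <- function(y, X, retention = c("kaiser", "cum85")) {
  retention <- match.arg(retention)
  Xs <- scale(X)
  ok_col <- apply(X, 2L, stats::sd) > 0
  Xs[, !ok_col] <- 0
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- if (retention == "kaiser") which(ev > 1) else {
    seq_len(which(cumsum(ev) / sum(ev) >= 0.85)[1])
  }
  if (length(keep) == 0L) keep <- 1L
  if (length(keep) >= length(y)) {
    stop("response_function: rank error, fewer years than retained components",
         call. = FALSE)
  }
  scores <- pc$x[, keep, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, scores), y)
  beta_pc <- fit$coefficients[-1]
  beta_pc[is.na(beta_pc)] <- 0
  as.vector(pc$rotation[, keep, drop = FALSE] %*% beta_pc)
}

#' Bootstrapped principal-component response function
#'
#' Regression of the chronology on the leading principal components of the
#' standardized monthly predictors (components retained by the Kaiser rule,
#' eigenvalue > 1, or a cumulative-85-percent rule), with coefficients
#' back-transformed to month space. The whole procedure, including the PCA
#' and the retention decision, is repeated on every paired-year bootstrap
#' resample; a slot is significant when its percentile interval excludes
#' zero.
#'
#' @inheritParams bootstrap_correlations
#' @param retention `"kaiser"` (default) or `"cum85"`.
#' @return A `response_result` data frame (coefficients are in standardized
#'   predictor units).
#' @export
response_function <- function(chron_index, predictors, n_boot = 1000L, seed,
                              level = 0.95, retention = "kaiser") {
  n <- length(chron_index)
  stopifnot(nrow(predictors) == n)
  if (n < 30L) stop("response_function: need >= 30 common years", call. = FALSE)
  coefs <- pc_regression_coef(chron_index, predictors, retention)
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, nrow = n_boot, ncol = ncol(predictors))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- tryCatch(
      pc_regression_coef(chron_index[idx], predictors[idx, , drop = FALSE],
                         retention),
      error = function(e) rep(NA_real_, ncol(predictors)))
  }
  alpha <- (1 - level) / 2
  lo <- apply(boot, 2L, stats::quantile, probs = alpha, na.rm = TRUE)
  hi <- apply(boot, 2L, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  structure(
    data.frame(slot = colnames(predictors), coefficient = coefs,
               lower = lo, upper = hi,
               significant = lo > 0 | hi < 0,
               p = NA_real_, flag = "ok", row.names = NULL),
    class = c("response_result", "data.frame"),
    kind = "response", n = n, n_boot = n_boot, seed = seed,
    retention = retention)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` with the linear influence of `z`
#' removed: `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' with a two-sided p-value from the t distribution on `n - 3` degrees of
#' freedom.
#'
#' @param x,y,z Numeric vectors of equal length (>= 10), each non-constant.
#' @return List with `estimate`, `p`, `n`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 10L) stop("partial_correlation: need >= 10 common years", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("partial_correlation: constant input series", call. = FALSE)
  }
  r_xy <- stats::cor(x, y); r_xz <- stats::cor(x, z); r_yz <- stats::cor(y, z)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12) {
    stop("partial_correlation: degenerate control, |r| with z is 1", call. = FALSE)
  }
  r <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  tt <- r * sqrt((n - 3) / (1 - r^2))
  list(estimate = r, p = 2 * stats::pt(-abs(tt), df = n - 3), n = n)
}

#' Write a response/correlation result to tidy CSV
#' @param result A `response_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_response_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result)[, c("slot", "coefficient", "lower",
                                             "upper", "significant")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
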