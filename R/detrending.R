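#' Fit a constrained negative-exponential growth curve
#'
#' Fits `y(t) = a * exp(-b * t) + d` by nonlinear least squares on the
#' cambial-age axis `t = 0, 1, ...` (years since the first measured ring;
#' no pith offsets are used). Missing rings (value 0) are excluded from the
#' fit. The fit is accepted only when `a > 0`, `b > 0` and the fitted curve
#' is strictly positive over the whole series span; otherwise (or on
#' non-convergence) the function returns `NULL`, and [detrend_series()]
#' applies its fallback cascade.
#'
#' Starting values: `a0` = first-decade mean minus last-decade mean (floored
#' at a small positive value), `b0 = 2 / n`, `d0` = last-decade mean; up to
#' 500 iterations at relative tolerance 1e-8.
#'
#' @param series A [measurement_series()].
#' @return A `growth_curve` of kind `"neg_exp"`, or `NULL` on failure.
#' @export
fit_negative_exponential <- function(series) {
  y_all <- series$values
  t_all <- seq_along(y_all) - 1
  ok <- y_all > 0
  if (sum(ok) < 10L) {
    stop("fit_negative_exponential: insufficient data, fewer than 10 non-missing values",
         call. = FALSE)
  }
  y <- y_all[ok]; t <- t_all[ok]
  n <- length(y)
  k <- max(1L, min(10L, floor(n / 3)))
  a0 <- max(mean(y[seq_len(k)]) - mean(y[seq.int(n - k + 1L, n)]),
            0.01 * abs(mean(y)), 1e-8)
  d0 <- mean(y[seq.int(n - k + 1L, n)])
  b0 <- 2 / n
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * t) + d,
                      start = list(a = a0, b = b0, d = d0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-8, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  if (!all(is.finite(p))) return(NULL)
  # a collapsing to ~0 relative to the series level means the exponential
  # component is unidentifiable (constant-like input): treat as failure
  if (p["a"] <= 1e-4 * mean(abs(y)) || p["b"] <= 0) return(NULL)
  curve <- p["a"] * exp(-p["b"] * t_all) + p["d"]
  if (any(curve <= 0)) return(NULL)
  growth_curve("neg_exp", a = unname(p["a"]), b = unname(p["b"]),
               d = unname(p["d"]))
}

#' Construct a growth-curve object
#'
#' @param kind One of `"neg_exp"`, `"linear"`, `"horizontal"`.
#' @param ... Parameters: `a`, `b`, `d` (neg_exp); `intercept`, `slope`
#'   (linear, slope must be <= 0); `mean` (horizontal).
#' @return A `growth_curve`.
#' @export
growth_curve <- function(kind = c("neg_exp", "linear", "horizontal"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  if (kind == "linear" && p$slope > 0) {
    stop("growth_curve: a positive-slope line is never used as a growth curve",
         call. = FALSE)
  }
  structure(c(list(kind = kind), p), class = "growth_curve")
}

#' Evaluate a growth curve on a cambial-age axis
#' @param curve A `growth_curve`.
#' @param t Cambial ages (0-based years since the first ring).
#' @return Fitted values.
#' @export
predict_growth_curve <- function(curve, t) {
  switch(curve$kind,
         neg_exp = curve$a * exp(-curve$b * t) + curve$d,
         linear = curve$intercept + curve$slope * t,
         horizontal = rep(curve$mean, length(t)))
}

#' @export
print.growth_curve <- function(x, ...) {
  pars <- switch(x$kind,
                 neg_exp = sprintf("a=%.4g b=%.4g d=%.4g", x$a, x$b, x$d),
                 linear = sprintf("intercept=%.4g slope=%.4g", x$intercept, x$slope),
                 horizontal = sprintf("mean=%.4g", x$mean))
  cat(sprintf("<growth_curve> %s (%s)\n", x$kind, pars))
  invisible(x)
}

#' Detrend one measurement series into a dimensionless index series
#'
#' Applies the classical conservative cascade: (1) constrained negative
#' exponential; (2) least-squares line, accepted only if its slope is
#' non-positive and the line stays strictly positive over the span; (3)
#' horizontal line at the series mean. Indices are ratios `value / curve`
#' (dimensionless, mean near 1 over the fitted span); missing rings (value
#' 0) keep index 0.
#'
#' @param series A [measurement_series()].
#' @return An `index_series`: list with `series_id`, `tree_id`,
#'   `first_year`, `indices` and the `curve` used.
#' @export
detrend_series <- function(series) {
  y <- series$values
  t <- seq_along(y) - 1
  ok <- y > 0
  if (!any(ok)) {
    stop("detrend_series: degenerate all-zero series ", series$series_id,
         call. = FALSE)
  }
  curve <- if (sum(ok) >= 10L) fit_negative_exponential(series) else NULL
  if (is.null(curve)) {
    if (sum(ok) >= 2L) {
      fit <- stats::lm.fit(cbind(1, t[ok]), y[ok])
      slope <- unname(fit$coefficients[2])
      intercept <- unname(fit$coefficients[1])
      line <- intercept + slope * t
      if (!is.na(slope) && slope <= 0 && all(line > 0)) {
        curve <- growth_curve("linear", intercept = intercept, slope = slope)
      }
    }
  }
  if (is.null(curve)) {
    curve <- growth_curve("horizontal", mean = mean(y[ok]))
  }
  fitted <- predict_growth_curve(curve, t)
  indices <- ifelse(ok, y / fitted, 0)
  structure(list(series_id = series$series_id, tree_id = series$tree_id,
                 first_year = series$first_year, indices = indices,
                 curve = curve),
            class = "index_series")
}

#' @export
print.index_series <- function(x, ...) {
  cat(sprintf("<index_series> %s (tree %s): %d years from %d, curve %s\n",
              x$series_id, x$tree_id, length(x$indices), x$first_year,
              x$curve$kind))
  invisible(x)
}

#' Detrend a collection of measurement series
#' @param series A list of [measurement_series()].
#' @return A list of `index_series`.
#' @export
detrend <- function(series) {
  out <- lapply(series, detrend_series)
  names(out) <- vapply(out, function(s) s$series_id, character(1))
  out
}
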