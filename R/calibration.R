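#' Fit the linear transfer function
#'
#' Ordinary least squares of the climate target on the chronology index
#' over the calibration years: `target = b0 + b1 * index`. The returned
#' model carries the calibration correlation `r`, explained variance `r2`,
#' regression `F = r2 (n - 2) / (1 - r2)` and residual standard error.
#'
#' @param index Annual chronology index over the calibration period.
#' @param target Annual climate values (degC) over the same years.
#' @param years Optional calendar years (used for labelling only).
#' @return A `transfer_model`.
#' @export
fit_transfer <- function(index, target, years = NULL) {
  n <- length(index)
  stopifnot(length(target) == n)
  if (n < 20L) stop("fit_transfer: need >= 20 common years", call. = FALSE)
  if (stats::sd(index) == 0) {
    stop("fit_transfer: singular fit, constant index", call. = FALSE)
  }
  fit <- stats::lm(target ~ index)
  r <- stats::cor(index, target)
  r2 <- r^2
  structure(
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         r = r, r2 = r2,
         F = r2 * (n - 2) / (1 - r2),
         se = summary(fit)$sigma,
         slope_se = summary(fit)$coefficients["index", "Std. Error"],
         n = n, calibration_years = years,
         calibration_mean = mean(target)),
    class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("<transfer_model> T = %.3f + %.3f * index  (n=%d, R=%.3f, r2=%.3f, F=%.3f)\n",
              x$intercept, x$slope, x$n, x$r, x$r2, x$F))
  invisible(x)
}

#' @export
predict.transfer_model <- function(object, index, ...) {
  object$intercept + object$slope * index
}

#' Leave-one-out cross-validation predictions
#'
#' For each year the model is refit on the remaining `n - 1` years and
#' used to predict the withheld year. Computed through the exact OLS
#' deletion identity `pred_loo_i = y_i - e_i / (1 - h_ii)`, which equals
#' the explicit refit.
#'
#' @inheritParams fit_transfer
#' @return Numeric vector of out-of-sample predictions, one per year.
#' @export
loocv_predict <- function(index, target) {
  n <- length(index)
  stopifnot(length(target) == n)
  if (n < 3L) stop("loocv_predict: insufficient years (need >= 3)", call. = FALSE)
  if (stats::sd(index) == 0) {
    stop("loocv_predict: singular fit, constant index", call. = FALSE)
  }
  fit <- stats::lm(target ~ index)
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  unname(target - stats::residuals(fit) / (1 - h))
}

#' Reduction of error (RE)
#'
#' `RE = 1 - sum((o - p)^2) / sum((o - mean_cal)^2)`: skill relative to the
#' calibration-mean (climatology) predictor. `RE = 1` is a perfect
#' prediction, `RE = 0` the no-skill benchmark, and positive values
#' indicate skill.
#'
#' @param observed,predicted Equal-length numeric vectors (degC).
#' @param calibration_mean Calibration-period mean of the observations.
#' @return RE (scalar, at most 1).
#' @export
reduction_of_error <- function(observed, predicted, calibration_mean) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  denom <- sum((observed - calibration_mean)^2)
  if (denom == 0) {
    stop("reduction_of_error: undefined denominator, observations all equal the calibration mean",
         call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / denom
}

#' Sign test on departures from the calibration mean
#'
#' Counts the years where observed and predicted departures from the
#' calibration mean agree in strict sign (agreements) versus disagree
#' (disagreements); years where either departure is exactly zero are
#' excluded from both counts. The binomial p-value against chance
#' (probability one half) is attached.
#'
#' @inheritParams reduction_of_error
#' @return List with `plus`, `minus`, `p`.
#' @export
sign_test <- function(observed, predicted, calibration_mean) {
  stopifnot(length(observed) == length(predicted))
  so <- sign(observed - calibration_mean)
  sp <- sign(predicted - calibration_mean)
  use <- so != 0 & sp != 0
  plus <- sum(so[use] == sp[use])
  minus <- sum(so[use] != sp[use])
  p <- if (plus + minus > 0) {
    stats::binom.test(plus, plus + minus, p = 0.5)$p.value
  } else NA_real_
  list(plus = plus, minus = minus, p = p)
}

#' Product-means test (PMT)
#'
#' Forms the departure products `q_i = (o_i - mean_cal)(p_i - mean_cal)`,
#' splits them into positive products (sign agreement) and absolute
#' negative products (disagreement), and contrasts the two group means with
#' a Welch-type t statistic
#' `t = (M+ - M-) / sqrt(S+^2/n+ + S-^2/n-)`.
#'
#' @inheritParams reduction_of_error
#' @return List with `t`, `p` (two-sided, Welch df), `n_plus`, `n_minus`.
#' @export
product_means_test <- function(observed, predicted, calibration_mean) {
  stopifnot(length(observed) == length(predicted))
  q <- (observed - calibration_mean) * (predicted - calibration_mean)
  pos <- q[q > 0]
  neg <- abs(q[q < 0])
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("product_means_test: degenerate split, all products share one sign (all-agreement)",
         call. = FALSE)
  }
  m_pos <- mean(pos); m_neg <- mean(neg)
  s_pos <- stats::sd(pos); s_neg <- stats::sd(neg)
  v <- s_pos^2 / length(pos) + s_neg^2 / length(neg)
  if (!is.finite(v) || v == 0) {
    stop("product_means_test: degenerate variance, both groups have zero spread",
         call. = FALSE)
  }
  t <- (m_pos - m_neg) / sqrt(v)
  df <- v^2 / (s_pos^4 / (length(pos)^2 * (length(pos) - 1)) +
                 s_neg^4 / (length(neg)^2 * (length(neg) - 1)))
  list(t = t, p = 2 * stats::pt(-abs(t), df = df),
       n_plus = length(pos), n_minus = length(neg))
}

#' Calibrate and verify a transfer function in one call
#'
#' Composes [fit_transfer()], [loocv_predict()] and the verification
#' battery: cross-validation correlation, reduction of error, sign test
#' and product-means test, all computed on the leave-one-out predictions
#' against the full-calibration mean.
#'
#' @inheritParams fit_transfer
#' @return List of class `verification` with elements `model` (the
#'   `transfer_model`) and `stats` (list: `r_cv`, `re`, `sign_plus`,
#'   `sign_minus`, `sign_p`, `pmt`, `pmt_p`, `loo_predictions`).
#' @export
verify <- function(index, target, years = NULL) {
  model <- fit_transfer(index, target, years = years)
  loo <- loocv_predict(index, target)
  cm <- model$calibration_mean
  st <- sign_test(target, loo, cm)
  pmt <- tryCatch(product_means_test(target, loo, cm),
                  error = function(e) list(t = NA_real_, p = NA_real_,
                                           n_plus = NA, n_minus = NA))
  structure(
    list(model = model,
         stats = list(r_cv = stats::cor(target, loo),
                      re = reduction_of_error(target, loo, cm),
                      sign_plus = st$plus, sign_minus = st$minus,
                      sign_p = st$p,
                      pmt = pmt$t, pmt_p = pmt$p,
                      loo_predictions = loo)),
    class = "verification")
}

#' @export
print.verification <- function(x, ...) {
  m <- x$model; s <- x$stats
  cat("Calibration / leave-one-out verification\n")
  cat(sprintf("  R      %8.3f\n  r2     %8.3f\n  F      %8.3f\n", m$r, m$r2, m$F))
  cat(sprintf("  Sign   %d+/%d-\n  RE     %8.3f\n  PMT    %8.3f\n",
              s$sign_plus, s$sign_minus, s$re, s$pmt))
  invisible(x)
}

#' Write a verification report as CSV
#' @param v A `verification` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_verification_csv <- function(v, path) {
  df <- data.frame(statistic = c("R", "r2", "F", "sign_plus", "sign_minus",
                                 "RE", "PMT", "r_cv"),
                   value = c(v$model$r, v$model$r2, v$model$F,
                             v$stats$sign_plus, v$stats$sign_minus,
                             v$stats$re, v$stats$pmt, v$stats$r_cv))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
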