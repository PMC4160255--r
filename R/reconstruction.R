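#' Reconstruct the climate target over the reliable chronology period
#'
#' Applies the transfer function `b0 + b1 * index` to every year of the
#' (already truncated) chronology, deliberately extending beyond the
#' calibration period. Mean and standard deviation are computed over the
#' full reconstructed span and drive the warm/cold event classification.
#'
#' @param model A `transfer_model`.
#' @param chron A `chronology` (its full span is reconstructed; truncate
#'   with [truncate_reliable()] first).
#' @param cutoff_years Low-pass cutoff period in years (default 10).
#' @param min_len Minimum warm/cold period length in years (default 5).
#' @return A `reconstruction`: data frame `year`, `value`, `filtered`,
#'   `event`, with attributes `mean`, `sigma`, `periods`, `percent`.
#' @export
reconstruct <- function(model, chron, cutoff_years = 10, min_len = 5L) {
  if (nrow(chron) == 0L) {
    stop("reconstruct: empty chronology (no reliable period)", call. = FALSE)
  }
  values <- predict(model, chron$index)
  rec <- structure(
    data.frame(year = chron$year, value = values,
               filtered = NA_real_, event = NA_character_),
    class = c("reconstruction", "data.frame"),
    mean = mean(values), sigma = stats::sd(values),
    cutoff_years = cutoff_years, min_len = min_len)
  rec <- classify_events(rec)
  rec$filtered <- lowpass_filter(rec$value, cutoff_years = cutoff_years)
  attr(rec, "periods") <- segment_periods(rec$filtered, attr(rec, "mean"),
                                          min_len = min_len,
                                          years = rec$year)
  rec
}

#' Classify warm, cold and normal years
#'
#' Labels each year by the one-sigma rule: warm when the value exceeds
#' `mean + sigma`, cold when below `mean - sigma`, normal otherwise.
#' Percentages are reported as rounded warm and cold shares with the
#' normal share as their complement to 100.
#'
#' @param recon A `reconstruction` (or any data frame with a `value`
#'   column; mean/sigma are computed if absent).
#' @return The reconstruction with its `event` column filled and a
#'   `percent` attribute `c(warm, cold, normal)`.
#' @export
classify_events <- function(recon) {
  v <- recon$value
  m <- attr(recon, "mean"); s <- attr(recon, "sigma")
  if (is.null(m)) m <- mean(v)
  if (is.null(s)) s <- stats::sd(v)
  if (is.na(s) || s == 0) {
    warning("classify_events: sigma is 0, all years classified normal")
    recon$event <- "normal"
    attr(recon, "percent") <- c(warm = 0, cold = 0, normal = 100)
    return(recon)
  }
  recon$event <- ifelse(v > m + s, "warm", ifelse(v < m - s, "cold", "normal"))
  warm_pct <- round(100 * sum(recon$event == "warm") / length(v))
  cold_pct <- round(100 * sum(recon$event == "cold") / length(v))
  attr(recon, "percent") <- c(warm = warm_pct, cold = cold_pct,
                              normal = 100 - warm_pct - cold_pct)
  attr(recon, "mean") <- m
  attr(recon, "sigma") <- s
  recon
}

#' Zero-phase low-pass filter
#'
#' Second-order Butterworth low-pass with cutoff frequency `1 / cutoff_years`
#' cycles per year, applied forward and backward (zero phase, so features
#' are not shifted in time). The series' least-squares line is removed
#' first and restored afterwards, and the residuals are padded by odd
#' reflection, so constants and linear trends pass through exactly and the
#' output has the input's length.
#'
#' @param values Annual series (length >= 3 * cutoff_years).
#' @param cutoff_years Half-power cutoff period in years (> 2; default 10).
#' @return Filtered series, same length as the input.
#' @export
lowpass_filter <- function(values, cutoff_years = 10) {
  if (cutoff_years <= 2) {
    stop("lowpass_filter: cutoff must exceed 2 years (Nyquist)", call. = FALSE)
  }
  n <- length(values)
  if (n < 3 * cutoff_years) {
    stop("lowpass_filter: series shorter than 3 * cutoff_years", call. = FALSE)
  }
  t <- seq_len(n)
  line_fit <- stats::lm.fit(cbind(1, t), values)
  line <- line_fit$coefficients[1] + line_fit$coefficients[2] * t
  x <- values - line
  bw <- signal::butter(2, (1 / cutoff_years) / 0.5, type = "low")
  pad <- min(n - 1L, as.integer(6 * cutoff_years))
  # odd (point-symmetric) reflection, the scipy filtfilt convention
  pre <- 2 * x[1] - x[(pad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(pre, x, post)
  y <- signal::filter(bw, ext)
  y <- rev(signal::filter(bw, rev(y)))
  y[(pad + 1L):(pad + n)] + line
}

#' Segment a filtered series into warm and cold periods
#'
#' Finds maximal runs of consecutive years strictly above (warm) or below
#' (cold) the reference mean. Runs of at least `min_len` years become
#' periods; shorter runs (and years exactly on the mean) are reported as
#' `"unclassified"` so that every year is covered exactly once.
#'
#' @param filtered Low-pass filtered annual values.
#' @param reference_mean Reference level on the same scale.
#' @param min_len Minimum period length in years (default 5).
#' @param years Optional calendar years (default `1:length`).
#' @return Data frame `start`, `end`, `phase`, `length`, ordered in time.
#' @export
segment_periods <- function(filtered, reference_mean, min_len = 5L,
                            years = seq_along(filtered)) {
  phase <- ifelse(filtered > reference_mean, "warm",
                  ifelse(filtered < reference_mean, "cold", "unclassified"))
  r <- rle(phase)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lab <- ifelse(r$values != "unclassified" & r$lengths >= min_len,
                r$values, "unclassified")
  data.frame(start = years[starts], end = years[ends], phase = lab,
             length = r$lengths)
}

#' @export
print.reconstruction <- function(x, ...) {
  p <- attr(x, "percent")
  cat(sprintf("<reconstruction> %d years %d-%d; mean %.2f, sigma %.2f\n",
              nrow(x), x$year[1], x$year[nrow(x)],
              attr(x, "mean"), attr(x, "sigma")))
  cat(sprintf("  warm %d%%, cold %d%%, normal %d%%\n", p["warm"], p["cold"],
              p["normal"]))
  invisible(x)
}

#' Write a reconstruction to CSV
#' @param recon A `reconstruction`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reconstruction_csv <- function(recon, path) {
  utils::write.csv(
    data.frame(year = recon$year, value = recon$value,
               filtered_value = recon$filtered, event_label = recon$event),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write warm/cold periods to CSV
#' @param recon A `reconstruction`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_periods_csv <- function(recon, path) {
  utils::write.csv(attr(recon, "periods"), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
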