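#' Construct a gridded annual field
#'
#' A year x lat x lon array of any scalar variable (temperature, cloud
#' cover, SST, a wind component). Missing values are `NA`, never silent
#' zeros. Vector fields are handled as two scalar fields.
#'
#' @param years Strictly increasing integer years (no duplicates).
#' @param lat,lon Strictly monotone coordinate axes.
#' @param values Numeric array `length(years) x length(lat) x length(lon)`.
#' @param units Unit string.
#' @return A `gridded_field`.
#' @export
gridded_field <- function(years, lat, lon, values, units = "unknown") {
  years <- as.integer(years)
  if (anyDuplicated(years) || is.unsorted(years, strictly = TRUE)) {
    stop("gridded_field: years must be strictly increasing with no duplicates",
         call. = FALSE)
  }
  mono <- function(a) all(diff(a) > 0) || all(diff(a) < 0)
  if (!mono(lat) || !mono(lon)) {
    stop("gridded_field: lat/lon axes must be strictly monotone", call. = FALSE)
  }
  if (!identical(dim(values), c(length(years), length(lat), length(lon)))) {
    stop("gridded_field: values must be a year x lat x lon array", call. = FALSE)
  }
  structure(list(years = years, lat = lat, lon = lon,
                 values = values, units = units),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field> %d years %d-%d, %d x %d grid [%s]\n",
              length(x$years), min(x$years), max(x$years),
              length(x$lat), length(x$lon), x$units))
  invisible(x)
}

#' Read a gridded field from long-form CSV
#'
#' Expects columns `year,lat,lon,value`; every (lat, lon) cell may cover a
#' different subset of years (absent combinations become `NA`).
#'
#' @param path CSV path.
#' @param units Unit string.
#' @return A `gridded_field`.
#' @export
read_field_csv <- function(path, units = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "lat", "lon", "value")
  if (!all(need %in% names(df))) {
    stop("read_field_csv: expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  years <- sort(unique(df$year)); lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  arr <- array(NA_real_, dim = c(length(years), length(lat), length(lon)))
  arr[cbind(match(df$year, years), match(df$lat, lat), match(df$lon, lon))] <-
    df$value
  gridded_field(years, lat, lon, arr, units = units)
}

#' Write a gridded map (lat x lon matrix) to CSV
#' @param map Matrix with lat rows and lon columns.
#' @param lat,lon Coordinate axes.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_map_csv <- function(map, lat, lon, path) {
  df <- expand.grid(lat = lat, lon = lon)
  df$value <- as.vector(map)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detrended spatial correlation map
#'
#' Per grid cell, removes the least-squares linear-in-year trend from both
#' the series and the cell values over their common years, then Pearson
#' correlates the residuals. Cells with fewer than `min_years` common
#' years are masked (`NA`).
#'
#' @param series Named annual values (names = calendar years).
#' @param field A [gridded_field()].
#' @param min_years Minimum common years per cell (default 20).
#' @return A `length(lat) x length(lon)` correlation matrix.
#' @export
detrended_spatial_correlation <- function(series, field, min_years = 20L) {
  syears <- as.integer(names(series))
  common_any <- FALSE
  out <- matrix(NA_real_, length(field$lat), length(field$lon))
  for (i in seq_along(field$lat)) {
    for (j in seq_along(field$lon)) {
      cell <- field$values[, i, j]
      ok <- !is.na(cell) & field$years %in% syears
      yrs <- field$years[ok]
      if (length(yrs) < min_years) next
      common_any <- TRUE
      a <- series[as.character(yrs)]
      b <- cell[ok]
      ra <- stats::lm.fit(cbind(1, yrs), a)$residuals
      rb <- stats::lm.fit(cbind(1, yrs), b)$residuals
      if (stats::sd(ra) == 0 || stats::sd(rb) == 0) next
      out[i, j] <- stats::cor(ra, rb)
    }
  }
  if (!common_any) {
    stop("detrended_spatial_correlation: no cell shares >= ", min_years,
         " years with the series", call. = FALSE)
  }
  out
}

#' Composite anomaly maps for extreme years
#'
#' Selects the `k` highest and `k` lowest years of the series (with
#' `k = round(n / 10)` when `k = "decile"`; ties broken by the earlier
#' year) and averages the field anomaly, relative to the base-period cell
#' mean, over each selection.
#'
#' @param series Named annual values (names = calendar years); all its
#'   years must be covered by the field.
#' @param field A [gridded_field()].
#' @param k `"decile"` or an explicit count.
#' @param base_years Years defining the anomaly base period (default: all
#'   series years).
#' @return List with `high` and `low` anomaly matrices, `high_years`,
#'   `low_years`, `k`.
#' @export
decile_composite <- function(series, field, k = "decile", base_years = NULL) {
  syears <- as.integer(names(series))
  if (!all(syears %in% field$years)) {
    stop("decile_composite: field does not cover all series years", call. = FALSE)
  }
  n <- length(series)
  kk <- if (identical(k, "decile")) as.integer(floor(n / 10 + 0.5)) else as.integer(k)
  if (kk > n / 2) stop("decile_composite: k exceeds half the years", call. = FALSE)
  ord_hi <- order(-series, syears)
  ord_lo <- order(series, syears)
  hi_years <- sort(syears[ord_hi[seq_len(kk)]])
  lo_years <- sort(syears[ord_lo[seq_len(kk)]])
  if (is.null(base_years)) base_years <- syears
  base_idx <- match(base_years, field$years)
  base_mean <- apply(field$values[base_idx, , , drop = FALSE], c(2, 3), mean,
                     na.rm = TRUE)
  comp <- function(yrs) {
    idx <- match(yrs, field$years)
    apply(field$values[idx, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE) -
      base_mean
  }
  list(high = comp(hi_years), low = comp(lo_years),
       high_years = hi_years, low_years = lo_years, k = kk)
}
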