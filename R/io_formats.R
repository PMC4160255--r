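#' Construct a single-core measurement series
#'
#' A `measurement_series` holds the dated annual measurements of one core:
#' ring width (conventionally 0.01 or 0.001 mm in Tucson files) or earlywood
#' density (g/cm3). The year axis is contiguous; dated missing rings are
#' encoded as value 0 and are excluded from log/ratio computations
#' downstream.
#'
#' @param series_id Core identifier (at most 8 characters for RWL export).
#' @param tree_id Tree identifier; several cores may share one tree.
#' @param first_year Calendar year of the first value.
#' @param values Numeric vector of non-negative annual measurements.
#' @param units Free-text unit string (e.g. `"0.01 mm"`, `"g/cm3"`).
#' @return An object of class `measurement_series`.
#' @export
measurement_series <- function(series_id, tree_id, first_year, values,
                               units = "unknown") {
  stopifnot(is.character(series_id), length(series_id) == 1L,
            is.character(tree_id), length(tree_id) == 1L)
  first_year <- as.integer(first_year)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("measurement_series: 'values' must contain at least one value",
         call. = FALSE)
  }
  if (anyNA(values)) {
    stop("measurement_series: NA values are not allowed; encode missing rings as 0",
         call. = FALSE)
  }
  if (any(values < 0)) {
    stop("measurement_series: negative measurements are not allowed", call. = FALSE)
  }
  structure(
    list(series_id = series_id, tree_id = tree_id,
         first_year = first_year, values = values, units = units),
    class = "measurement_series")
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("<measurement_series> %s (tree %s): %d years %d-%d [%s]\n",
              x$series_id, x$tree_id, length(x$values),
              x$first_year, last_year(x), x$units))
  invisible(x)
}

#' Last calendar year of a measurement series
#' @param x A `measurement_series`.
#' @return Integer year.
#' @export
last_year <- function(x) x$first_year + length(x$values) - 1L

#' Calendar years covered by a measurement series
#' @param x A `measurement_series`.
#' @return Integer vector of years.
#' @export
series_years <- function(x) seq.int(x$first_year, last_year(x))

# infer a tree id from an RWL series id: strip one trailing core letter,
# the usual field convention (e.g. "SMS01A" -> "SMS01")
infer_tree_id <- function(series_id) {
  stripped <- sub("[A-Za-z]$", "", series_id)
  ifelse(nchar(stripped) > 0L, stripped, series_id)
}

#' Read a Tucson/RWL decadal measurement file
#'
#' Parses the decadal exchange format used by the ITRDB: an 8-character
#' series id, the decade year, then up to ten integer values per line, the
#' series terminated by a stop marker. The marker doubles as a units flag:
#' `999` means values are 0.01 mm, `-9999` means 0.001 mm. Header lines (the
#' occasional three-line site preamble) are skipped. Values are returned in
#' file units, untransformed.
#'
#' @param path Path to an RWL file.
#' @param tree_ids Either `NULL` (infer tree ids by stripping a trailing
#'   core letter from the series id) or a named character vector mapping
#'   series id to tree id.
#' @return A list of [measurement_series()].
#' @export
read_rwl <- function(path, tree_ids = NULL) {
  if (!file.exists(path)) stop("read_rwl: file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("read_rwl: empty file: ", path, call. = FALSE)
    return(list())
  }

  acc <- list()     # per-series accumulator: list(first_year, values, closed, units)
  order_seen <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    id <- trimws(substr(line, 1L, 8L))
    rest <- trimws(substr(line, 9L, nchar(line)))
    toks <- strsplit(rest, "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) < 2L || is.na(suppressWarnings(as.numeric(toks[1])))) {
      # tolerate site-metadata header lines (non-numeric after the id field)
      next
    }
    decade <- suppressWarnings(as.integer(toks[1]))
    vals <- suppressWarnings(as.numeric(toks[-1]))
    if (anyNA(vals)) {
      stop(sprintf("read_rwl: malformed decade line %d in %s", i, path),
           call. = FALSE)
    }
    if (length(vals) > 10L) {
      stop(sprintf("read_rwl: more than 10 values on line %d in %s", i, path),
           call. = FALSE)
    }
    units <- NA_character_
    stop_at <- which(vals == 999 | vals == -9999)
    if (length(stop_at) > 0L) {
      k <- stop_at[length(stop_at)]        # marker is last numeric token
      units <- if (vals[k] == -9999) "0.001 mm" else "0.01 mm"
      vals <- vals[seq_len(k - 1L)]
    }
    if (is.null(acc[[id]])) {
      acc[[id]] <- list(first_year = decade, values = numeric(0),
                        closed = FALSE, units = "0.01 mm",
                        next_year = decade)
      order_seen <- c(order_seen, id)
    }
    st <- acc[[id]]
    if (st$closed) {
      stop(sprintf("read_rwl: duplicate data for series '%s' after its stop marker (line %d)",
                   id, i), call. = FALSE)
    }
    if (length(st$values) > 0L && decade != st$next_year) {
      if (decade < st$next_year) {
        stop(sprintf("read_rwl: duplicate (series, year) block for '%s' at line %d",
                     id, i), call. = FALSE)
      }
      stop(sprintf("read_rwl: non-contiguous decade line %d for series '%s'",
                   i, id), call. = FALSE)
    }
    st$values <- c(st$values, vals)
    st$next_year <- st$first_year + length(st$values)
    if (!is.na(units)) {
      st$units <- units
      st$closed <- TRUE
    }
    acc[[id]] <- st
  }

  out <- lapply(order_seen, function(id) {
    st <- acc[[id]]
    tid <- if (!is.null(tree_ids)) {
      if (is.na(tree_ids[id])) stop("read_rwl: no tree id supplied for series ", id,
                                    call. = FALSE)
      unname(tree_ids[id])
    } else {
      infer_tree_id(id)
    }
    measurement_series(id, tid, st$first_year, st$values, units = st$units)
  })
  names(out) <- order_seen
  out
}

#' Write measurement series to a Tucson/RWL decadal file
#'
#' Rows are decade-aligned; each series ends with the stop marker implied by
#' its units (`999` for 0.01 mm, `-9999` for 0.001 mm, `999` otherwise).
#' Values are written as integers, so the round trip through [read_rwl()] is
#' exact for integer-valued data (the format stores integers by definition).
#'
#' @param series A list of [measurement_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rwl <- function(series, path) {
  if (inherits(series, "measurement_series")) series <- list(series)
  lines <- character(0)
  for (s in series) {
    if (nchar(s$series_id) > 8L) {
      stop("write_rwl: series id longer than 8 characters: ", s$series_id,
           call. = FALSE)
    }
    marker <- if (identical(s$units, "0.001 mm")) -9999L else 999L
    yrs <- series_years(s)
    vals <- as.integer(round(s$values))
    tokens <- c(as.character(vals), as.character(marker))
    tok_year <- c(yrs, yrs[length(yrs)] + 1L)
    row_start <- unique(tok_year - (tok_year %% 10L))
    for (dec in row_start) {
      in_row <- tok_year >= dec & tok_year < dec + 10L
      if (!any(in_row)) next
      first <- min(tok_year[in_row])
      lines <- c(lines, sprintf("%-8s%4d%s", s$series_id, first,
                                paste0(sprintf("%6s", tokens[in_row]),
                                       collapse = "")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read long-form measurement CSV
#'
#' The canonical interchange format for density series: columns
#' `series_id,tree_id,year,value`. Each series must be contiguous in year.
#'
#' @param path CSV path.
#' @param units Unit string recorded on every series (default `"g/cm3"`).
#' @return A list of [measurement_series()].
#' @export
read_measurement_csv <- function(path, units = "g/cm3") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "tree_id", "year", "value")
  if (!all(need %in% names(df))) {
    stop("read_measurement_csv: expected columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  ids <- unique(df$series_id)
  out <- lapply(ids, function(id) {
    d <- df[df$series_id == id, ]
    d <- d[order(d$year), ]
    if (anyDuplicated(d$year)) {
      stop("read_measurement_csv: duplicate (series, year) in series ", id,
           call. = FALSE)
    }
    if (!all(diff(d$year) == 1L)) {
      stop("read_measurement_csv: non-contiguous years in series ", id,
           call. = FALSE)
    }
    measurement_series(as.character(id), as.character(d$tree_id[1]),
                       d$year[1], d$value, units = units)
  })
  names(out) <- ids
  out
}

#' Write measurement series to long-form CSV
#' @param series A list of [measurement_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_measurement_csv <- function(series, path) {
  if (inherits(series, "measurement_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(series_id = s$series_id, tree_id = s$tree_id,
               year = series_years(s), value = s$values)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a monthly climate table
#'
#' One row per calendar year with columns `year, m1..m12`. Years must be
#' strictly increasing and contiguous; missing cells are rejected (the
#' calibration machinery assumes complete station records). Temperatures
#' must lie inside physical bounds (-90, 60) degC and precipitation must be
#' non-negative.
#'
#' @param df Data frame with columns `year, m1..m12`.
#' @param variable One of `"tmax"`, `"tmean"`, `"tmin"`, `"precip"`.
#' @param units Unit string (`"degC"` or `"mm"` typically).
#' @return A data frame of class `climate_table`.
#' @export
climate_table <- function(df, variable = c("tmax", "tmean", "tmin", "precip"),
                          units = NULL) {
  variable <- match.arg(variable)
  if (is.null(units)) units <- if (variable == "precip") "mm" else "degC"
  need <- c("year", paste0("m", 1:12))
  if (!identical(names(df), need)) {
    stop("climate_table: schema error, expected columns year,m1..m12",
         call. = FALSE)
  }
  df$year <- as.integer(df$year)
  vals <- as.matrix(df[, -1])
  if (anyNA(vals) || anyNA(df$year)) {
    stop("climate_table: missing cells are not allowed", call. = FALSE)
  }
  dy <- diff(df$year)
  if (any(dy != 1L)) {
    gaps <- unlist(mapply(function(a, b) seq(a + 1L, b - 1L),
                          df$year[which(dy > 1L)], df$year[which(dy > 1L) + 1L],
                          SIMPLIFY = FALSE))
    if (length(gaps)) {
      stop("climate_table: gap error, missing years: ",
           paste(gaps, collapse = ", "), call. = FALSE)
    }
    stop("climate_table: years must be strictly increasing", call. = FALSE)
  }
  if (variable == "precip") {
    if (any(vals < 0)) stop("climate_table: negative precipitation", call. = FALSE)
  } else {
    if (any(vals <= -90 | vals >= 60)) {
      stop("climate_table: temperature outside physical bounds (-90, 60) degC",
           call. = FALSE)
    }
  }
  structure(df, class = c("climate_table", "data.frame"),
            variable = variable, units = units)
}

#' Read a wide monthly climate CSV
#'
#' Expects a header `year,m1,...,m12` and one complete row per year.
#'
#' @param path CSV path.
#' @param variable Climate variable name; see [climate_table()].
#' @param units Optional unit override.
#' @return A `climate_table`.
#' @export
read_climate_csv <- function(path, variable, units = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) != 13L) {
    stop(sprintf("read_climate_csv: schema error, expected 13 columns, got %d",
                 ncol(df)), call. = FALSE)
  }
  names(df) <- c("year", paste0("m", 1:12))
  climate_table(df, variable = variable, units = units)
}

#' Write a climate table to wide CSV
#' @param climate A `climate_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_climate_csv <- function(climate, path) {
  utils::write.csv(as.data.frame(climate), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.climate_table <- function(x, ...) {
  cat(sprintf("<climate_table> %s [%s], %d years %d-%d\n",
              attr(x, "variable"), attr(x, "units"), nrow(x),
              x$year[1], x$year[nrow(x)]))
  invisible(x)
}
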