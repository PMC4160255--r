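#' Tukey biweight robust mean
#'
#' Iteratively reweighted location estimate with biweight weights
#' `w = (1 - u^2)^2` for `|u| < 1`, `u = (x - m) / (c * S)`, `c = 9` and `S`
#' the median absolute deviation from the current estimate. Starts at the
#' median and iterates until `|delta m| < 1e-8 * (1 + |m|)` or 50
#' iterations. If the MAD is 0 the median is returned.
#'
#' @param values Numeric vector of finite values, length >= 1.
#' @param c Tuning constant (default 9, the chronology-building standard).
#' @return The biweight location estimate.
#' @export
biweight_mean <- function(values, c = 9) {
  if (length(values) == 0L) {
    stop("biweight_mean: empty input", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("biweight_mean: values must be finite", call. = FALSE)
  }
  m <- stats::median(values)
  for (it in seq_len(50L)) {
    S <- stats::median(abs(values - m))
    if (S == 0) return(m)
    u <- (values - m) / (c * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * values) / sum(w)
    if (abs(m_new - m) < 1e-8 * (1 + abs(m))) return(m_new)
    m <- m_new
  }
  m
}

#' Expressed population signal (EPS)
#'
#' `EPS = n * rbar / (n * rbar + (1 - rbar))`: the expected correlation of
#' an n-sample mean chronology with the hypothetical population chronology,
#' squared. Non-positive `rbar` maps to 0.
#'
#' @param n Number of series (or trees, depending on convention).
#' @param rbar Mean inter-series correlation.
#' @return EPS in `[0, 1]`.
#' @export
eps_formula <- function(n, rbar) {
  ifelse(rbar <= 0, 0, n * rbar / (n * rbar + (1 - rbar)))
}

# stack index series into a year x series matrix (NA outside coverage),
# with parallel tree-id lookup
index_matrix <- function(indices) {
  first <- min(vapply(indices, function(s) s$first_year, integer(1)))
  last <- max(vapply(indices, function(s) s$first_year + length(s$indices) - 1L,
                     numeric(1)))
  years <- seq.int(first, last)
  mat <- matrix(NA_real_, nrow = length(years), ncol = length(indices),
                dimnames = list(years,
                                vapply(indices, function(s) s$series_id,
                                       character(1))))
  for (j in seq_along(indices)) {
    s <- indices[[j]]
    rows <- s$first_year - first + seq_along(s$indices)
    mat[rows, j] <- s$indices
  }
  list(years = years, mat = mat,
       tree = vapply(indices, function(s) s$tree_id, character(1)))
}

#' Running Rbar and EPS over gliding windows
#'
#' For each window, `rbar` is the mean of all pairwise Pearson correlations
#' between series having at least `window / 2` common years inside the
#' window; `n` is the mean number of such series present per year; EPS
#' follows [eps_formula()]. Windows with fewer than two qualifying series
#' are flagged as undefined; windows with `rbar <= 0` report EPS 0 with a
#' low-signal flag.
#'
#' @param indices A list of `index_series`.
#' @param window Window length in years (>= 10), default 30.
#' @param overlap Overlap between consecutive windows in years (< window),
#'   default 15 (50 percent, a continuous gliding trace).
#' @param n_mode `"cores"` (default) counts every series as one sample in
#'   the EPS `n`; `"trees"` uses the number of distinct trees.
#' @return Data frame with one row per window: `start`, `end`, `rbar`,
#'   `n`, `n_trees_min`, `n_cores_min`, `eps`, `flag`.
#' @export
running_rbar_eps <- function(indices, window = 30L, overlap = 15L,
                             n_mode = c("cores", "trees")) {
  n_mode <- match.arg(n_mode)
  stopifnot(window >= 10L, overlap < window)
  step <- window - overlap
  im <- index_matrix(indices)
  years <- im$years
  starts <- seq.int(years[1], max(years[1], years[length(years)] - window + 1L),
                    by = step)
  if (starts[length(starts)] + window - 1L < years[length(years)]) {
    starts <- c(starts, years[length(years)] - window + 1L)
  }
  res <- lapply(starts, function(st) {
    en <- st + window - 1L
    rows <- which(years >= st & years <= en)
    sub <- im$mat[rows, , drop = FALSE]
    cover <- colSums(!is.na(sub) & sub != 0)
    use <- which(cover >= window / 2)
    n_per_year <- rowSums(!is.na(sub[, use, drop = FALSE]))
    if (length(use) < 2L) {
      return(data.frame(start = st, end = en, rbar = NA_real_,
                        n = length(use), n_trees_min = NA_real_,
                        n_cores_min = NA_real_, eps = NA_real_,
                        flag = "undefined"))
    }
    cm <- suppressWarnings(stats::cor(sub[, use, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    rbar <- mean(cm[upper.tri(cm)], na.rm = TRUE)
    n <- if (n_mode == "cores") mean(n_per_year) else {
      mean(apply(!is.na(sub[, use, drop = FALSE]), 1L,
                 function(p) length(unique(im$tree[use][p]))))
    }
    depth <- per_year_depth(im, rows)
    eps <- eps_formula(n, rbar)
    flag <- if (rbar <= 0) "low_signal" else "ok"
    data.frame(start = st, end = en, rbar = rbar, n = n,
               n_trees_min = min(depth$n_trees), n_cores_min = min(depth$n_cores),
               eps = eps, flag = flag)
  })
  do.call(rbind, res)
}

# per-year core and tree counts for a subset of rows of an index matrix
per_year_depth <- function(im, rows = seq_along(im$years)) {
  present <- !is.na(im$mat[rows, , drop = FALSE])
  n_cores <- rowSums(present)
  n_trees <- apply(present, 1L, function(p) length(unique(im$tree[p])))
  data.frame(year = im$years[rows], n_cores = n_cores, n_trees = n_trees)
}

#' Build a standard site chronology
#'
#' Averages detrended index series year by year with the Tukey biweight
#' robust mean (missing-ring zeros participate as values; years covered by
#' no series inside the union span raise a coverage-gap error), tallies
#' per-year core and tree counts, and attaches the running Rbar/EPS trace.
#' Per-year `rbar` and `eps` columns carry the value of the window whose
#' centre is nearest the year.
#'
#' @param indices A list of `index_series` (>= 2).
#' @param window,overlap,n_mode Passed to [running_rbar_eps()].
#' @param eps_threshold Reliability threshold on EPS (default 0.80).
#' @param eps_override EPS floor for the depth-based override (default
#'   0.75): a window with `eps >= eps_override` and at least
#'   `override_trees` trees still counts as reliable.
#' @param override_trees Minimum trees for the override (default 4).
#' @param min_trees,min_cores Depth floor for the reliable period
#'   (defaults 4 trees, 6 cores).
#' @return A data frame of class `chronology` with columns `year`, `index`,
#'   `n_cores`, `n_trees`, `rbar`, `eps`; attributes `windows` (the
#'   [running_rbar_eps()] table), `reliable_from` and the rule parameters.
#' @export
build_chronology <- function(indices, window = 30L, overlap = 15L,
                             n_mode = "cores",
                             eps_threshold = 0.80, eps_override = 0.75,
                             override_trees = 4L, min_trees = 4L,
                             min_cores = 6L) {
  if (length(indices) < 2L) {
    stop("build_chronology: need at least 2 index series", call. = FALSE)
  }
  im <- index_matrix(indices)
  covered <- rowSums(!is.na(im$mat))
  if (any(covered == 0L)) {
    stop("build_chronology: coverage-gap error, no series covers year(s) ",
         paste(im$years[covered == 0L], collapse = ", "), call. = FALSE)
  }
  idx <- apply(im$mat, 1L, function(x) biweight_mean(x[!is.na(x)]))
  depth <- per_year_depth(im)
  win <- running_rbar_eps(indices, window = window, overlap = overlap,
                          n_mode = n_mode)
  centers <- (win$start + win$end) / 2
  nearest <- vapply(im$years, function(y) which.min(abs(centers - y)), integer(1))
  chron <- data.frame(year = im$years, index = idx,
                      n_cores = depth$n_cores, n_trees = depth$n_trees,
                      rbar = win$rbar[nearest], eps = win$eps[nearest])
  rownames(chron) <- NULL
  chron <- structure(chron, class = c("chronology", "data.frame"),
                     windows = win,
                     eps_threshold = eps_threshold,
                     eps_override = eps_override,
                     override_trees = override_trees,
                     min_trees = min_trees, min_cores = min_cores)
  attr(chron, "reliable_from") <- reliable_from_year(chron)
  chron
}

# earliest year from which the reliability rule holds through the end;
# NA when no year qualifies
reliable_from_year <- function(chron) {
  eps_ok <- !is.na(chron$eps) &
    (chron$eps > attr(chron, "eps_threshold") |
       (chron$eps >= attr(chron, "eps_override") &
          chron$n_trees >= attr(chron, "override_trees")))
  ok <- eps_ok & chron$n_trees >= attr(chron, "min_trees") &
    chron$n_cores >= attr(chron, "min_cores")
  bad <- which(!ok)
  from <- if (length(bad) == 0L) 1L else if (max(bad) == nrow(chron)) NA_integer_ else max(bad) + 1L
  if (is.na(from)) NA_integer_ else chron$year[from]
}

#' Truncate a chronology to its reliable period
#'
#' Keeps the sub-chronology from the earliest year where the reliability
#' rule -- EPS above the threshold (or the override: EPS at or above the
#' override floor with enough trees) AND the depth floor (default 4 trees
#' and 6 cores) -- holds continuously to the end. The per-window decision
#' trail is attached as attribute `decision_trail`.
#'
#' @param chron A `chronology`.
#' @return The truncated `chronology`.
#' @export
truncate_reliable <- function(chron) {
  from <- attr(chron, "reliable_from")
  if (is.na(from)) {
    stop("truncate_reliable: empty-reliable-period error, no year satisfies the rule",
         call. = FALSE)
  }
  win <- attr(chron, "windows")
  win$eps_ok <- !is.na(win$eps) &
    (win$eps > attr(chron, "eps_threshold") |
       (win$eps >= attr(chron, "eps_override") &
          win$n_trees_min >= attr(chron, "override_trees")))
  keep <- chron$year >= from
  out <- chron[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("windows", "eps_threshold", "eps_override", "override_trees",
              "min_trees", "min_cores")) {
    attr(out, a) <- attr(chron, a)
  }
  attr(out, "reliable_from") <- from
  attr(out, "decision_trail") <- win
  class(out) <- class(chron)
  out
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology> %d years %d-%d; depth %d-%d cores; reliable from %s\n",
              nrow(x), x$year[1], x$year[nrow(x)],
              min(x$n_cores), max(x$n_cores),
              ifelse(is.na(attr(x, "reliable_from")), "never",
                     attr(x, "reliable_from"))))
  invisible(x)
}

#' Export a chronology as CSV
#' @param chron A `chronology`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chronology_csv <- function(chron, path) {
  utils::write.csv(as.data.frame(chron)[, c("year", "index", "n_cores", "n_trees")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a chronology as crn-like fixed-width text
#'
#' Year, index scaled by 1000, and core depth, one row per year.
#' @param chron A `chronology`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_chronology_crn <- function(chron, path) {
  writeLines(sprintf("%6d%6d%4d", chron$year, as.integer(round(chron$index * 1000)),
                     chron$n_cores), path)
  invisible(path)
}
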