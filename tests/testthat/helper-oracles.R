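# standalone brute-force biweight loop, independent of the package's
# convergence logic (fixed 200 iterations, no tolerance test)
bw_oracle <- function(x, c = 9) {
  m <- stats::median(x)
  for (i in 1:200) {
    S <- stats::median(abs(x - m))
    if (S == 0) return(m)
    u <- (x - m) / (c * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    m <- sum(w * x) / sum(w)
  }
  m
}

# random integer-valued measurement series for RWL round trips
random_width_series <- function(id, seed) {
  set.seed(seed)
  n <- sample(15:60, 1)
  first <- sample(1800:1990, 1)
  measurement_series(id, infer_tree_id_pub(id), first,
                     sample(10:400, n, replace = TRUE), units = "0.01 mm")
}
infer_tree_id_pub <- function(id) sub("[A-Za-z]$", "", id)

# white-noise index series around 1 for chronology tests
noise_index_series <- function(id, tree, first, n, sd = 0.1) {
  structure(list(series_id = id, tree_id = tree, first_year = as.integer(first),
                 indices = 1 + stats::rnorm(n, 0, sd),
                 curve = growth_curve("horizontal", mean = 1)),
            class = "index_series")
}

# index series from an explicit vector
make_index_series <- function(id, tree, first, values) {
  structure(list(series_id = id, tree_id = tree, first_year = as.integer(first),
                 indices = as.numeric(values),
                 curve = growth_curve("horizontal", mean = 1)),
            class = "index_series")
}
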