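# Independent brute-force DTW oracle: exhaustively enumerates every
# admissible monotone boundary-to-boundary path on the cost grid with the
# symmetric step weighting (1, 2, 1) and returns the minimum total cost.
# Exponential-time by construction; usable only for short series.
dtw_brute_force <- function(ref, query) {
  n <- length(ref); m <- length(query)
  d <- abs(outer(ref, query, `-`))
  best <- Inf
  rec <- function(i, j, cost) {
    if (i == n && j == m) {
      if (cost < best) best <<- cost
      return(invisible(NULL))
    }
    if (i < n) rec(i + 1L, j, cost + d[i + 1L, j])
    if (j < m) rec(i, j + 1L, cost + d[i, j + 1L])
    if (i < n && j < m) rec(i + 1L, j + 1L, cost + 2 * d[i + 1L, j + 1L])
  }
  rec(1L, 1L, 2 * d[1L, 1L])
  best
}

# total cost of a given path re-accumulated from first principles
path_cost <- function(ref, query, path) {
  d <- abs(ref[path$ref_idx] - query[path$query_idx])
  w <- c(2, ifelse(diff(path$ref_idx) + diff(path$query_idx) == 2L, 2, 1))
  sum(w * d)
}
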