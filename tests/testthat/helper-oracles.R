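# Independent brute-force oracles used across test files. These deliberately
# avoid the package's cumsum-based aggregation path.

brute_block_sums <- function(v, n, stride) {
  starts <- seq.int(1L, length(v) - n + 1L, by = stride)
  vapply(starts, function(s) sum(v[s:(s + n - 1L)]), numeric(1))
}

brute_window_count <- function(N, width, step) {
  count <- 0L
  p <- 1L
  while (p + width - 1L <= N) {
    count <- count + 1L
    p <- p + step
  }
  count
}

# all permutations of 1:3, for exhaustive small-sample rank enumeration
perm3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
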