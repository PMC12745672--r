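# independent oracles, kept deliberately separate from the package's
# implementation paths

# direct double-loop evaluation of weighted (directed) modularity; used to
# check modularity_q, which is vectorised per community
modularity_direct <- function(W, labels) {
  diag(W) <- 0
  m <- sum(W)
  if (m <= 0) return(0)
  s_out <- rowSums(W); s_in <- colSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j])
      q <- q + W[i, j] / m - s_out[i] * s_in[j] / m^2
  }
  q
}

# enumerate all set partitions of n items (restricted growth strings) and
# return the maximal modularity over them
exhaustive_best_q <- function(W) {
  n <- nrow(W)
  stopifnot(n <= 10)
  best <- -Inf
  labels <- integer(n)
  recurse <- function(i, kmax) {
    if (i > n) {
      q <- modularity_q(W, labels[seq_len(n)])
      if (q > best) best <<- q
      return(invisible())
    }
    for (lab in seq_len(kmax + 1L)) {
      labels[i] <<- lab
      recurse(i + 1L, max(kmax, lab))
    }
  }
  recurse(1L, 0L)
  best
}
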