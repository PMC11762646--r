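# Independent oracles used to freeze expected values. These never call the
# package code paths they check.

# Plug-in MI by direct summation over the cells of a joint count matrix.
mi_oracle <- function(joint) {
  n <- sum(joint)
  total <- 0
  for (i in seq_len(nrow(joint))) {
    for (j in seq_len(ncol(joint))) {
      pij <- joint[i, j] / n
      if (pij > 0) {
        pi_ <- sum(joint[i, ]) / n
        p_j <- sum(joint[, j]) / n
        total <- total + pij * log(pij / (pi_ * p_j))
      }
    }
  }
  total
}

# Shannon entropy of a count vector, by direct summation.
entropy_oracle <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n)
# unordered draws from a universe in which items 1..K are successes.
hyper_tail_oracle <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  successes <- colSums(draws <= K)
  mean(successes >= k)
}

# Riemann zeta by partial series summation with an integral tail bound:
# sum_{x>N} x^-s  ~  N^(1-s)/(s-1) + N^(-s)/2, accurate far below 1e-10
# for N = 1e6 and s >= 1.5.
zeta_series_oracle <- function(s, N = 1e6) {
  sum((1:N)^(-s)) + N^(1 - s) / (s - 1) + N^(-s) / 2
}

# Sample from a geometric distribution on support {1, 2, ...}.
rgeom1 <- function(n, p, seed) {
  withr::with_seed(seed, stats::rgeom(n, p) + 1L)
}
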