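# Independent brute-force oracles for the distance kernels.

# Energy distance via the literal double sums over all ordered pairs
# (including self-pairs).
brute_energy <- function(x, y) {
  2 * mean(outer(x, y, function(a, b) abs(a - b))) -
    mean(outer(x, x, function(a, b) abs(a - b))) -
    mean(outer(y, y, function(a, b) abs(a - b)))
}

# 1-D earth mover's distance via the quantile-function L1 integral:
# split [0,1] at every i/n and j/m and sum |Q_x(u) - Q_y(u)| du piecewise.
brute_emd <- function(x, y) {
  xs <- sort(x)
  ys <- sort(y)
  n <- length(xs)
  m <- length(ys)
  u <- sort(unique(c(seq_len(n) / n, seq_len(m) / m)))
  lo <- c(0, u[-length(u)])
  qx <- xs[ceiling(pmax(lo, 1e-15) * n + 1e-12)]
  qy <- ys[ceiling(pmax(lo, 1e-15) * m + 1e-12)]
  sum(abs(qx - qy) * (u - lo))
}

# Adjusted Rand index between two partitions (contingency-table formula).
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  idx <- ch2(as.numeric(tab))
  e <- ch2(rowSums(tab)) * ch2(colSums(tab)) / ch2(sum(tab))
  mx <- (ch2(rowSums(tab)) + ch2(colSums(tab))) / 2
  if (mx == e) return(1)
  (idx - e) / (mx - e)
}
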