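# Independent brute-force implementations of the agreement statistics,
# written as plain loops over the definitions so they share no code with the
# package's vectorized versions.

ccc_brute <- function(x, y) {
  n <- length(x)
  mx <- 0; my <- 0
  for (i in seq_len(n)) { mx <- mx + x[i] / n; my <- my + y[i] / n }
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx2 <- sx2 + (x[i] - mx)^2 / n
    sy2 <- sy2 + (y[i] - my)^2 / n
    sxy <- sxy + (x[i] - mx) * (y[i] - my) / n
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

weighted_kappa_brute <- function(a, b, k) {
  # a, b are 0-based codes
  n <- length(a)
  tab <- matrix(0, k, k)
  for (i in seq_len(n)) tab[a[i] + 1, b[i] + 1] <- tab[a[i] + 1, b[i] + 1] + 1
  tab <- tab / n
  po <- 0; pe <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- 1 - (i - j)^2 / (k - 1)^2
    po <- po + w * tab[i, j]
    pe <- pe + w * sum(tab[i, ]) * sum(tab[, j])
  }
  (po - pe) / (1 - pe)
}
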