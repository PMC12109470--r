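# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: direct double loops over the definitions.

# Sample-entropy pair counting by exhaustive enumeration.
sampenOracle <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dmax <- 0
      for (k in 0:(m - 1)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
      if (dmax <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

# Higuchi curve lengths by direct summation of the definition.
higuchiOracle <- function(x, kmax) {
  n <- length(x)
  vapply(1:kmax, function(k) {
    Lm <- vapply(1:k, function(m) {
      M <- (n - m) %/% k
      if (M < 1) return(0)
      s <- 0
      for (i in 1:M) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      s * (n - 1) / (M * k) / k
    }, numeric(1))
    mean(Lm)
  }, numeric(1))
}

# AUC by exhaustive positive-negative pair counting (ties count 1/2).
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
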