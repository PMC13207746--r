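# Independent enumeration oracle for the one-sided exact test.
#
# Enumerates every 2x2 table with the same margins as [[a, b], [c, d]] and
# sums the exact conditional probability
#   (a+b)! (c+d)! (a+c)! (b+d)! / (n! a'! b'! c'! d'!)
# over tables at least as extreme in the requested direction. Probabilities
# are built from plain factorial products (no lchoose / dhyper), so the
# arithmetic route is independent of the package implementation.
fet_oracle <- function(a, b, c, d, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  const <- factorial(r1) * factorial(r2) * factorial(c1) * factorial(c2) /
    factorial(n)
  total <- 0
  for (ai in 0:min(r1, c1)) {
    bi <- r1 - ai; ci <- c1 - ai; di <- r2 - ci
    if (bi < 0 || ci < 0 || di < 0) next
    extreme <- if (direction == "positive") di >= d else ci >= c
    if (!extreme) next
    total <- total + const /
      (factorial(ai) * factorial(bi) * factorial(ci) * factorial(di))
  }
  min(1, total)
}

# all probabilities of the conditional family for fixed margins, indexed by
# the a-cell from max(0, c1-r2) to min(r1, c1); used by the exhaustive sweep
fet_oracle_family <- function(r1, r2, c1) {
  kmin <- max(0, c1 - r2)
  kmax <- min(r1, c1)
  if (kmax < kmin) return(numeric())
  n <- r1 + r2
  const <- factorial(r1) * factorial(r2) * factorial(c1) *
    factorial(n - c1) / factorial(n)
  vapply(kmin:kmax, function(k) {
    const / (factorial(k) * factorial(r1 - k) * factorial(c1 - k) *
               factorial(r2 - c1 + k))
  }, numeric(1))
}
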