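# Small, fast phantom specs shared across tests.

quickSpec <- function(...) {
  phantomSpec(shape = c(32L, 32L, 8L), spacing = c(2, 2, 4),
              radii = c(16, 11, 9), ...)
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# rank-based AUC of a score against binary labels
aucOf <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# angle (degrees) between an estimated linear map and a reference rotation
rotationErrorDeg <- function(Aest, Rtrue) {
  E <- Aest %*% solve(Rtrue)
  sv <- svd(E)
  R <- sv$u %*% t(sv$v)
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
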