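# Brute-force binomial-summation oracle for the outer safety level:
# P[at least r of n observations fall below the q-quantile]
# = sum_{k=r}^{n} C(n,k) q^k (1-q)^(n-k), summed term by term.
binom_tail_oracle <- function(r, n, q) {
  k <- r:n
  sum(choose(n, k) * q^k * (1 - q)^(n - k))
}

# Exhaustive scan for the tolerance-limit ranks using only the oracle.
scan_outer_tl <- function(n, q = 0.05, confidence = 0.95) {
  ok <- vapply(1:n, function(r) binom_tail_oracle(r, n, q) >= confidence,
               logical(1))
  if (!any(ok)) return(NA_integer_)
  max(which(ok))
}

scan_inner_tl <- function(n, q = 0.05, confidence = 0.95) {
  ok <- vapply(1:n, function(r) (1 - binom_tail_oracle(r, n, q)) >= confidence,
               logical(1))
  if (!any(ok)) return(NA_integer_)
  min(which(ok))
}
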