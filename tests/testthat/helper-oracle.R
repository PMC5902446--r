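# brute-force oracles, independent of the package's optimizer

# max log-likelihood of a single exponential over a dense log-spaced grid
gridMaxExp1 <- function(tau) {
  ks <- exp(seq(log(1e-3), log(10), length.out = 2001))
  max(vapply(ks, function(k) sum(log(k) - k * tau), numeric(1)))
}

# max log-likelihood of a 2-exponential mixture by a refining grid search
gridMaxExp2 <- function(tau) {
  best <- -Inf
  top <- c(NA, NA, NA)
  ks <- exp(seq(log(1e-3), log(10), length.out = 61))
  ps <- seq(0.02, 0.98, length.out = 25)
  for (rounds in 1:3) {
    for (k1 in ks) for (k2 in ks) {
      if (k2 >= k1) next
      for (p in ps) {
        ll <- sum(log(p * k1 * exp(-k1 * tau) + (1 - p) * k2 * exp(-k2 * tau)))
        if (ll > best) {
          best <- ll
          top <- c(k1, k2, p)
        }
      }
    }
    ks <- sort(unique(c(
      exp(seq(log(top[1]) - 0.15, log(top[1]) + 0.15, length.out = 15)),
      exp(seq(log(top[2]) - 0.15, log(top[2]) + 0.15, length.out = 15)))))
    ps <- seq(max(0.01, top[3] - 0.08), min(0.99, top[3] + 0.08),
              length.out = 17)
  }
  best
}
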