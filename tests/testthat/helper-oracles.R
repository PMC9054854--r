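# Brute-force oracles used by several test files. Each is written from
# first principles, independently of the implementation it checks.

# exact HWE: enumerate every genotype configuration with the observed
# allele counts; sum normalized multinomial probabilities of
# configurations no more likely than the observed one
hwe_enum_oracle <- function(a, h, b) {
  n <- a + h + b
  na <- 2 * a + h
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hets, function(hh) {
    aa <- (na - hh) / 2
    bb <- n - aa - hh
    if (aa < 0 || bb < 0) return(0)
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(hh) - lfactorial(bb) +
          hh * log(2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == h]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

# hypergeometric upper tail P(X >= k) by direct summation
hyper_upper_oracle <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(j)
    choose(K, j) * choose(N - K, n - j) / choose(N, n), numeric(1)))
}

# dosage matrix with tight LD blocks: SNPs within a block are noisy copies
# of one core vector; blocks are mutually independent
make_blocks <- function(n, sizes, flip = 0.02) {
  G <- NULL
  for (s in sizes) {
    core <- rbinom(n, 2, 0.4)
    block <- replicate(s, {
      x <- core
      sw <- runif(n) < flip
      x[sw] <- sample(0:2, sum(sw), replace = TRUE)
      x
    })
    G <- cbind(G, block)
  }
  G
}
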