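# Shared fixtures and independent oracles, built in code.

hammingMatrix <- function() distortionMatrix(matrix(c(0, 1, 1, 0), 2))

# binary entropy, written out independently of the package implementation
hb <- function(p) ifelse(p <= 0 | p >= 1, 0, -p * log2(p) - (1 - p) * log2(1 - p))

# rate (bits) and distortion of an explicit codebook, by the double sum
bruteRate <- function(q, px) {
  r <- as.vector(px %*% q)
  term <- function(v) sum(ifelse(v > 0, v * log2(v), 0))
  -term(r) + sum(px * apply(q, 1, term))
}
bruteDistortion <- function(q, px, d) sum(px * rowSums(q * d))

# random small distortion matrix with zero diagonal
randomSmallMatrix <- function(n, seed, scale = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n, 0.2, 2) * scale, n, n)
    diag(m) <- 0
    distortionMatrix(m)
  })
}

# random row-stochastic codebooks (Dirichlet-by-normalized-exponentials)
randomCodebooks <- function(n, count, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(count), function(i) {
      q <- matrix(stats::rexp(n * n), n, n)
      q / rowSums(q)
    })
  })
}

exactLagrangian <- function(cb, dm, beta, p) {
  rateOf(cb, p) * log(2) + beta * distortionOf(cb, dm, p)
}
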