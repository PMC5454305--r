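test_that("baStep fixed points and symmetry behave as the update dictates", {
  u <- uniformSource(2)
  ham <- hammingMatrix()
  cb <- uniformCodebook(2)
  # beta = 0: exp(0) weights leave the uniform codebook alone
  cb0 <- baStep(ham, 0, cb, u)
  expect_equal(conditional(cb0), conditional(cb))
  # symmetric matrix + symmetric init: the marginal stays uniform at any beta
  for (b in c(0.3, 1, 5)) {
    cbb <- baStep(ham, b, cb, u)
    expect_equal(outputMarginal(cbb), c(0.5, 0.5))
    expect_lt(max(abs(rowSums(conditional(cbb)) - 1)), 1e-12)
  }
  # beta = ln 3 fixed point: p(correct) = 1/(1 + e^-beta) = 3/4
  pt <- solveRDPoint(ham, log(3), keepCodebook = TRUE)
  expect_equal(diag(conditional(pt@codebook)), c(0.75, 0.75), tolerance = 1e-9)
  expect_equal(pt@distortion, 0.25, tolerance = 1e-9)
})

test_that("rate and distortion of explicit codebooks match direct evaluation", {
  u4 <- uniformSource(4)
  ident <- new("Codebook", conditional = diag(4), marginal = rep(0.25, 4))
  expect_equal(rateOf(ident, u4), 2)
  flat <- uniformCodebook(4)
  expect_equal(rateOf(flat, u4), 0)
  u2 <- uniformSource(2)
  q <- matrix(c(0.75, 0.25, 0.25, 0.75), 2, byrow = TRUE)
  cb <- new("Codebook", conditional = q, marginal = c(0.5, 0.5))
  expect_equal(rateOf(cb, u2), 1 - hb(0.25), tolerance = 1e-9)
  ham <- hammingMatrix()
  expect_equal(distortionOf(cb, ham, u2), 0.25)
  expect_equal(distortionOf(uniformCodebook(2), ham, u2), 0.5)
  expect_equal(distortionOf(new("Codebook", conditional = diag(2),
                                marginal = c(0.5, 0.5)), ham, u2), 0)
})

test_that("solveRDPoint reaches the binary closed form and its limits", {
  ham <- hammingMatrix()
  pt0 <- solveRDPoint(ham, 0)
  expect_equal(pt0@rateBits, 0)
  expect_equal(pt0@distortion, mean(costs(ham)))   # uniform fixed point
  ptBig <- solveRDPoint(ham, 30)
  expect_gt(ptBig@rateBits, 1 - 1e-6)
  expect_lt(ptBig@distortion, 1e-6)
  expect_equal(nEff(ptBig), 2^ptBig@rateBits)
  pt <- solveRDPoint(ham, log(3))
  expect_equal(pt@rateBits, 1 - hb(0.25), tolerance = 1e-6)
  expect_equal(pt@distortion, 0.25, tolerance = 1e-9)
})

test_that("Lagrangian never increases across baStep iterations", {
  for (k in 1:20) {
    n <- 2 + (k %% 4)
    dm <- randomSmallMatrix(n, seed = 500 + k)
    beta <- withr::with_seed(600 + k, stats::runif(1, 0, 20))
    u <- uniformSource(n)
    cb <- uniformCodebook(n)
    lag <- exactLagrangian(cb, dm, beta, u)
    for (i in 1:40) {
      cb <- baStep(dm, beta, cb, u)
      lag2 <- exactLagrangian(cb, dm, beta, u)
      expect_lte(lag2, lag + 1e-10)
      lag <- lag2
    }
  }
})

test_that("solver matches brute-force search over row-stochastic codebooks", {
  u2 <- uniformSource(2)
  dm2 <- randomSmallMatrix(2, seed = 71)
  res <- solveAtDistortion(dm2, 0.3 * dMaxUseful(dm2))
  grid <- seq(0, 1, by = 0.01)
  best <- Inf
  for (a in grid) for (b in grid) {
    q <- matrix(c(a, 1 - a, b, 1 - b), 2, byrow = TRUE)
    if (bruteDistortion(q, probs(u2), costs(dm2)) <= res$point@distortion + 1e-9)
      best <- min(best, bruteRate(q, probs(u2)))
  }
  expect_lte(res$point@rateBits, best + 1e-3)

  u3 <- uniformSource(3)
  dm3 <- randomSmallMatrix(3, seed = 72)
  res3 <- solveAtDistortion(dm3, 0.4 * dMaxUseful(dm3))
  best3 <- Inf
  for (q in randomCodebooks(3, 20000, seed = 73)) {
    if (bruteDistortion(q, probs(u3), costs(dm3)) <= res3$point@distortion + 1e-9)
      best3 <- min(best3, bruteRate(q, probs(u3)))
  }
  expect_lte(res3$point@rateBits, best3 + 1e-3)
})

test_that("swept curves tile the distortion axis, end at zero rate, stay monotone and convex", {
  for (s in 1:5) {
    dm <- randomSmallMatrix(8, seed = 900 + s)
    crv <- sweepCurve(dm, nPoints = 9)
    pts <- curvePoints(crv)
    expect_lte(pts$rate_bits[nrow(pts)], 1e-6)          # max-distortion endpoint
    expect_true(all(diff(pts$rate_bits) <= 1e-6))       # monotone
    expect_true(all(pts$rate_bits <= log2(8) + 1e-9))
    expect_true(all(pts$distortion >= -1e-12))
    # achieved distortions approximate the even grid (to the bisection tolerance)
    dmax <- dMaxUseful(dm)
    inner <- pts$distortion[seq_len(nrow(pts) - 1)]
    expect_lt(max(abs(inner - seq(0, dmax, length.out = 9)[-9])), 2e-4 * dmax)
    # convexity: every interior point on or below the chord of its neighbours
    for (i in 2:(nrow(pts) - 1)) {
      span <- pts$distortion[i + 1] - pts$distortion[i - 1]
      if (span < 1e-12) next
      w <- (pts$distortion[i] - pts$distortion[i - 1]) / span
      chord <- (1 - w) * pts$rate_bits[i - 1] + w * pts$rate_bits[i + 1]
      expect_lte(pts$rate_bits[i], chord + 1e-6)
    }
  }
})

test_that("degenerate all-zero environment collapses to the origin", {
  zero <- distortionMatrix(matrix(0, 3, 3))
  crv <- sweepCurve(zero, nPoints = 5)
  pts <- curvePoints(crv)
  expect_identical(nrow(pts), 1L)
  expect_equal(pts$rate_bits, 0)
  expect_equal(pts$distortion, 0)
})

test_that("curve CSV round-trips with its sidecar", {
  dm <- randomSmallMatrix(4, seed = 77)
  crv <- sweepCurve(dm, nPoints = 6)
  path <- file.path(withr::local_tempdir(), "curve.csv")
  writeRDCurve(crv, path, solverConfig = list(max_iter = 1000))
  back <- readRDCurve(path)
  expect_equal(curvePoints(back)$rate_bits, curvePoints(crv)$rate_bits,
               tolerance = 1e-12)
  expect_identical(back@envRef, crv@envRef)
  expect_identical(back@envRef, matrixHash(dm))
})
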