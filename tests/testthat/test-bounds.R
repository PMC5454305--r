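test_that("quantile bound matches its closed form and diverges at the confound", {
  expect_equal(quantileUpperBound(1), 0)
  expect_equal(quantileUpperBound(1 - exp(-0.001)), log2(1 / (1 - exp(-0.001))))
  expect_equal(quantileUpperBound(1 - exp(-0.01)), log2(1 / (1 - exp(-0.01))))
  expect_lt(abs(quantileUpperBound(1 - exp(-0.001)) - 9.97), 0.01)
  expect_lt(abs(quantileUpperBound(1 - exp(-0.01)) - 6.65), 0.01)
  expect_identical(quantileUpperBound(0), Inf)
  expect_error(quantileUpperBound(1.5), "domain")
  expect_error(quantileUpperBound(-0.1), "domain")
})

test_that("synonym bound counts percepts below the tolerance, self included", {
  dm <- distortionMatrix(matrix(c(0, 3, 1, 0), 2))   # d(1,2)=1, d(2,1)=3
  expect_equal(synonymUpperBound(dm, 2), 0.5)
  expect_equal(synonymUpperBound(dm, 10), 0)          # everything a synonym
  expect_equal(synonymUpperBound(dm, 0.5), 1)         # only self: log2 N
  rnd <- randomSmallMatrix(7, seed = 41)
  expect_equal(synonymUpperBound(rnd, dMin(rnd) / 2), log2(7))
  expect_error(synonymUpperBound(rnd, 0), "domain")
})

test_that("uniform-allocation bound equals the rate of its explicit codebook", {
  expect_equal(uniformAllocBound(4, 0, 1), list(rate_bits = 2, distortion = 0))
  expect_equal(uniformAllocBound(2, 0.5, 1)$rate_bits, 0)
  b <- uniformAllocBound(4, 0.25, 1)
  expect_equal(b$rate_bits, 2 - hb(0.25) - 0.25 * log2(3), tolerance = 1e-12)
  expect_equal(b$distortion, 0.25)
  # internal consistency oracle: rateOf on the constructed codebook
  for (nc in list(c(4, 0.25), c(6, 0.1), c(3, 0.6))) {
    n <- nc[1]; C <- nc[2]
    q <- matrix(C / (n - 1), n, n)
    diag(q) <- 1 - C
    cb <- new("Codebook", conditional = q, marginal = rep(1 / n, n))
    expect_equal(uniformAllocBound(n, C, 1)$rate_bits,
                 rateOf(cb, uniformSource(n)), tolerance = 1e-12)
  }
  expect_error(uniformAllocBound(4, 1.2, 1), "domain")
})

test_that("uniform-environment lower bound matches the Hamming closed form", {
  expect_equal(uniformEnvRD(2, 0, 1), 1)
  expect_equal(uniformEnvRD(16, 0, 2), 4)
  expect_equal(uniformEnvRD(2, 0.25, 1), 1 - hb(0.25), tolerance = 1e-12)
  expect_equal(uniformEnvRD(8, 1 * 7 / 8, 1), 0)   # zero-rate endpoint
  expect_equal(uniformEnvRD(8, 3, 1), 0)           # past the endpoint
  expect_error(uniformEnvRD(8, 0.5, 0), "domain")
})

test_that("asymptotic bracket has the stated endpoints and ordering", {
  ab <- asymptoticBounds(1024, 0.5, 1, 2)
  expect_equal(ab$lo_bits, 5)
  expect_equal(ab$hi_bits, 7.5)
  expect_equal(asymptoticBounds(64, 0, 1, 3),
               list(lo_bits = 6, hi_bits = 6))
  abEq <- asymptoticBounds(32, 0.3, 1.5, 1.5)
  expect_equal(abEq$lo_bits, abEq$hi_bits)
  for (D in c(0.1, 0.4, 0.9)) {
    ab <- asymptoticBounds(100, D, 1, 2.5)
    expect_lte(ab$lo_bits, ab$hi_bits)
  }
  expect_error(asymptoticBounds(100, 1.2, 1, 2), "regime")
})

test_that("required gain follows (C / (<d> - D)) log2 N", {
  expect_equal(requiredGain(1, 2, 1, 4), 2)
  base <- requiredGain(0.5, 3, 1, 8)
  expect_equal(requiredGain(0.5, 3, 1, 64), 2 * base)       # linear in log2 N
  expect_equal(requiredGain(0.5, 5, 1, 8), base / 2)        # doubling <d> - D
  expect_error(requiredGain(1, 2, 2.5, 4), "domain")
})

test_that("Gaussian closed form switches off at D = sigma^2", {
  expect_equal(gaussianRD(1, 1), 0)
  expect_equal(gaussianRD(1, 0.25), 1)
  expect_equal(gaussianRD(2, 0.5), 1)
  expect_equal(gaussianRD(4, 0.5), 1.5)
  # monotone increasing in sigma^2 at fixed D
  expect_true(all(diff(vapply(c(1, 2, 4, 8), gaussianRD, 0, D = 0.5)) > 0))
  expect_error(gaussianRD(-1, 0.5), "domain")
  expect_error(gaussianRD(1, 0), "domain")
})

test_that("bounds report labels the regime and carries every bound", {
  dm <- drawMatrix(environmentSpec("exponential", shift = 1, nStates = 25L,
                                   seed = 3L))
  repHi <- boundsReport(dm, 0.5)
  expect_identical(repHi$regime, "high-fidelity")
  expect_true(all(c("quantile_ub", "synonym_ub", "uniform_alloc_ub",
                    "uniform_env_lb", "asym_lo", "asym_hi",
                    "required_beta") %in% names(repHi)))
  expect_identical(repHi$quantile_ub, Inf)   # no entry below the confound
  repLo <- boundsReport(dm, 2)
  expect_identical(repLo$regime, "low-fidelity")
  expect_null(repLo$asym_lo)
  path <- file.path(withr::local_tempdir(), "bounds.json")
  boundsReport(dm, 0.5, path = path)
  expect_true(file.exists(path))
})
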