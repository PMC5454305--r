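test_that("drawn matrices have zero diagonal, shifted support and reproduce bit-identically", {
  for (fam in c("exponential", "lognormal", "correlated_exponential")) {
    sp <- environmentSpec(fam, shift = 1, nStates = 30L, seed = 11L)
    dm <- drawMatrix(sp)
    expect_identical(diag(costs(dm)), rep(0, 30))
    off <- costs(dm)[row(costs(dm)) != col(costs(dm))]
    expect_true(all(off >= 1))
    expect_identical(costs(dm), costs(drawMatrix(sp)))
    dm2 <- drawMatrix(environmentSpec(fam, shift = 1, nStates = 30L, seed = 12L))
    expect_false(identical(costs(dm), costs(dm2)))
  }
})

test_that("invalid specs are rejected", {
  expect_error(environmentSpec("exponential", nStates = 1L, seed = 1L), "nStates")
  expect_error(environmentSpec("exponential", scaleParams = list(mean = -1),
                               nStates = 5L, seed = 1L), "mean")
  expect_error(environmentSpec("exponential", shift = -0.5, nStates = 5L,
                               seed = 1L), "shift")
  expect_error(environmentSpec("weibull", nStates = 5L, seed = 1L))
  expect_error(distortionMatrix(matrix(c(1, 2, 2, 1), 2)), "diagonal")
})

test_that("off-diagonal sample mean matches the ensemble mean (law of large numbers)", {
  se <- 1 / sqrt(100 * 99)   # exponential(mean 1): SD 1, N(N-1) entries
  for (s in 1:5) {
    dm <- drawMatrix(environmentSpec("exponential", shift = 0,
                                     scaleParams = list(mean = 1),
                                     nStates = 100L, seed = s))
    expect_lt(abs(meanOffDiag(dm) - 1), 3 * se)
  }
})

test_that("minimal confound is the smallest off-diagonal entry", {
  expect_identical(minimalConfound(distortionMatrix(matrix(c(0, 3, 2, 0), 2))), 2)
  dm20 <- drawMatrix(environmentSpec("exponential", shift = 20, nStates = 10L,
                                     seed = 4L))
  expect_gte(minimalConfound(dm20), 20)
  # min of 39800 unit exponentials sits within 0.01 of the shift
  for (s in 1:5) {
    dm <- drawMatrix(environmentSpec("exponential", shift = 1, nStates = 200L,
                                     seed = s))
    expect_gte(minimalConfound(dm), 1)
    expect_lte(minimalConfound(dm), 1.01)
    expect_lte(minimalConfound(dm), meanOffDiag(dm))
  }
})

test_that("maximal useful distortion is the best zero-rate column cost", {
  expect_equal(dMaxUseful(hammingMatrix()), 0.5)
  expect_equal(dMaxUseful(distortionMatrix(matrix(c(0, 5, 1, 0), 2))), 0.5)
  for (s in 1:10) {
    dm <- randomSmallMatrix(6, seed = 100 + s)
    expect_lte(dMaxUseful(dm), mean(costs(dm)))
  }
  # non-uniform source: weighted column means
  dm <- distortionMatrix(matrix(c(0, 5, 1, 0), 2))
  p <- new("SourceDistribution", probs = c(0.9, 0.1))
  expect_equal(dMaxUseful(dm, p), min(c(0.9 * 0 + 0.1 * 5, 0.9 * 1 + 0.1 * 0)))
})

test_that("correlateMatrix averages pairs, keeps the floor and the mean", {
  const <- distortionMatrix(matrix(2, 4, 4) - diag(2, 4))
  expect_equal(costs(correlateMatrix(const, seed = 5L)), costs(const))

  dm <- drawMatrix(environmentSpec("exponential", shift = 1, nStates = 100L,
                                   seed = 21L))
  dmc <- correlateMatrix(dm, seed = 8L)
  expect_identical(diag(costs(dmc)), rep(0, 100))
  expect_gte(dMin(dmc), dMin(dm))

  off <- function(m) costs(m)[row(costs(m)) != col(costs(m))]
  prt <- dmc@metadata$pairings
  expect_length(prt, 100 * 99)
  expect_true(all(prt != seq_along(prt)))
  # replacement rule and induced pairwise correlation, from the recorded pairing
  expect_equal(off(dmc), (off(dm) + off(dm)[prt]) / 2)
  expect_gt(cor(off(dmc), off(dmc)[prt]), 0)
  # exchangeable averaging preserves the ensemble mean in expectation
  expect_lt(abs(mean(off(dmc)) - mean(off(dm))), 3 * sd(off(dm)) / sqrt(length(prt)))
})

test_that("lognormal calibration hits the requested quantile", {
  pref <- 1 - exp(-0.001)   # exponential(mean 1) CDF at 0.001
  sp <- calibrateLognormal(pref, 0.001, logSd = 1, nStates = 20L, seed = 1L)
  expect_lt(abs(plnorm(0.001, sp@scaleParams$meanlog, sp@scaleParams$sdlog) - pref),
            1e-10)
  # location decreases as the required low-cost mass increases
  spLo <- calibrateLognormal(0.01, 0.5, logSd = 1, nStates = 20L, seed = 1L)
  spHi <- calibrateLognormal(0.2, 0.5, logSd = 1, nStates = 20L, seed = 1L)
  expect_lt(spHi@scaleParams$meanlog, spLo@scaleParams$meanlog)
  expect_error(calibrateLognormal(1.2, 0.5, nStates = 20L, seed = 1L),
               "calibration failure")
  expect_error(calibrateLognormal(0.5, -1, nStates = 20L, seed = 1L),
               "calibration failure")
})

test_that("matrix CSV round-trips with its spec sidecar", {
  sp <- environmentSpec("lognormal", shift = 0,
                        scaleParams = list(meanlog = -2, sdlog = 1.5),
                        nStates = 12L, seed = 33L)
  dm <- drawMatrix(sp)
  path <- file.path(withr::local_tempdir(), "m.csv")
  writeDistortionMatrix(dm, path)
  back <- readDistortionMatrix(path)
  expect_equal(costs(back), costs(dm))
  expect_identical(back@spec@family, "lognormal")
  expect_identical(costs(drawMatrix(back@spec)), costs(dm))
})
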