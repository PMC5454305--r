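#' Read a swept curve at a fixed distortion
#'
#' Piecewise-linear, order-preserving interpolation of rate at distortion D
#' on a swept \linkS4class{RDCurve}. Values outside the curve's distortion
#' span are refused rather than extrapolated.
#'
#' @param curve an \linkS4class{RDCurve}.
#' @param D distortion at which to read the rate.
#' @return rate in bits.
#' @export
rateAtDistortion <- function(curve, D) {
  stopifnot(is(curve, "RDCurve"))
  pts <- curve@points
  if (D < min(pts$distortion) - 1e-12 || D > max(pts$distortion) + 1e-12)
    stop(sprintf("extrapolation error: D = %.6g outside the swept span [%.6g, %.6g]",
                 D, min(pts$distortion), max(pts$distortion)))
  if (nrow(pts) == 1L) return(pts$rate_bits)
  agg <- stats::aggregate(rate_bits ~ distortion, data = pts, FUN = min)
  stats::approx(agg$distortion, agg$rate_bits, xout = D, ties = "ordered",
                rule = 1)$y
}

#' Fraction-of-guessing distortion targets
#'
#' Translates "D equal to f of the average cost of random guessing" into
#' absolute distortion units, \eqn{D = f \langle d \rangle}, with the
#' all-entries mean (including the zero diagonal) available as an
#' alternative denominator; the two coincide as N grows.
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param fraction fraction(s) of the mean distortion, e.g. 0.01 for 1\%.
#' @param denominator \code{"off_diagonal"} (default) or \code{"all_entries"}.
#' @return absolute distortion target(s).
#' @export
distortionFraction <- function(d, fraction,
                               denominator = c("off_diagonal", "all_entries")) {
  denominator <- match.arg(denominator)
  base <- if (denominator == "off_diagonal") meanOffDiag(d) else mean(costs(d))
  fraction * base
}

#' Percentile bootstrap interval for the mean
#'
#' Resamples the values with replacement \code{nBoot} times, takes the mean
#' of each resample, and returns the percentile interval at the requested
#' level (default 68\%). Deterministic under the seed.
#'
#' @param values numeric vector (>= 2 values).
#' @param level interval mass in (0, 1); default 0.68.
#' @param nBoot number of resamples; default 1000.
#' @param seed integer seed.
#' @return named numeric: \code{low}, \code{high}.
#' @export
bootstrapCI <- function(values, level = 0.68, nBoot = 1000L, seed = 1L) {
  if (length(values) < 2L)
    stop("insufficient data: bootstrapCI needs at least 2 values")
  stopifnot(level > 0, level < 1, nBoot >= 1L)
  n <- length(values)
  means <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = nBoot)
    rowMeans(matrix(values[idx], nrow = nBoot))
  })
  qs <- stats::quantile(means, probs = c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  c(low = min(qs[1], mean(values)), high = max(qs[2], mean(values)))
}

#' Minimal gain achieving a target distortion
#'
#' The smallest gain beta whose converged codebook reaches expected
#' distortion at or below the target, found by the bisection of
#' \code{\link{solveAtDistortion}}. This is the metabolic-efficiency price
#' of fidelity: in the high-fidelity regime it grows linearly with
#' \eqn{\log_2 N}, in the low-fidelity regime it asymptotes.
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param Dtarget target distortion, strictly between 0 and the maximal
#'   useful distortion.
#' @param p a \linkS4class{SourceDistribution}; defaults to uniform.
#' @param ... solver settings passed to \code{\link{solveAtDistortion}}.
#' @return the minimal gain (numeric scalar).
#' @export
requiredGainEmpirical <- function(d, Dtarget, p = uniformSource(nStates(d)), ...) {
  dmax <- dMaxUseful(d, p)
  if (!(Dtarget > 0 && Dtarget < dmax))
    stop("Dtarget must lie strictly between 0 and the maximal useful distortion")
  res <- solveAtDistortion(d, Dtarget, p, ...)
  if (is.na(res$betaRequired)) 0 else res$betaRequired
}

#' Run an ensemble experiment over environment sizes
#'
#' For each environment size N and each sample, draws a matrix from the
#' ensemble and measures the optimal rate (and the gain used) at each target
#' distortion; cells aggregate the mean rate with a percentile-bootstrap
#' confidence interval. Per-sample seeds derive deterministically from the
#' root seed, so the run is reproducible and order-independent. Targets
#' above a draw's maximal useful distortion are recorded as rate 0 with
#' \code{flagged = TRUE}.
#'
#' Two measurement modes: \code{"target"} (default) bisects the gain
#' directly at each target distortion; \code{"curve"} sweeps a full
#' \code{nPoints}-point curve per draw and interpolates, as when tracing
#' whole rate-distortion functions.
#'
#' @param family,shift,scaleParams ensemble identity, see
#'   \code{\link{environmentSpec}}.
#' @param Nlist integer vector of environment sizes.
#' @param Dtargets positive distortion targets (absolute units).
#' @param nSamples draws per N (>= 2).
#' @param seed root seed.
#' @param mode \code{"target"} or \code{"curve"}.
#' @param nPoints sweep resolution for \code{mode = "curve"}.
#' @param level,nBoot bootstrap interval settings.
#' @param maxIter,tol,dTolFrac solver settings.
#' @return an \linkS4class{EnsembleSummary}.
#' @export
runEnsemble <- function(family = "exponential", shift = 1,
                        scaleParams = NULL,
                        Nlist = c(20L, 50L, 100L),
                        Dtargets = c(0.5, 1.5),
                        nSamples = 10L, seed = 1L,
                        mode = c("target", "curve"), nPoints = 15L,
                        level = 0.68, nBoot = 1000L,
                        maxIter = 1000L, tol = 1e-10, dTolFrac = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(nSamples >= 2L, all(Dtargets > 0))
  rows <- list()
  for (n in Nlist) {
    for (i in seq_len(nSamples)) {
      s <- deriveSeed(seed, sprintf("%s_shift%g_N%d", family, shift, n), i)
      dm <- drawMatrix(environmentSpec(family, shift = shift,
                                       scaleParams = scaleParams,
                                       nStates = n, seed = s))
      dmax <- dMaxUseful(dm)
      crv <- if (mode == "curve")
        sweepCurve(dm, nPoints = nPoints, maxIter = maxIter, tol = tol,
                   dTolFrac = dTolFrac)
      for (D in Dtargets) {
        if (D >= dmax) {
          rate <- 0; beta <- 0; flagged <- TRUE
        } else if (mode == "target") {
          res <- solveAtDistortion(dm, D, maxIter = maxIter, tol = tol,
                                   dTolFrac = dTolFrac)
          rate <- res$point@rateBits
          beta <- if (is.na(res$betaRequired)) 0 else res$betaRequired
          flagged <- FALSE
        } else {
          rate <- rateAtDistortion(crv, D)
          beta <- requiredGainEmpirical(dm, D, maxIter = maxIter, tol = tol,
                                        dTolFrac = dTolFrac)
          flagged <- FALSE
        }
        rows[[length(rows) + 1L]] <- data.frame(
          family = family, shift = shift, N = n, D_target = D,
          sample = i, seed = s, rate_bits = rate, beta = beta,
          flagged = flagged, matrix_hash = matrixHash(dm),
          stringsAsFactors = FALSE)
      }
    }
  }
  smp <- do.call(rbind, rows)
  cellKeys <- unique(smp[, c("N", "D_target")])
  cellRows <- lapply(seq_len(nrow(cellKeys)), function(k) {
    sel <- smp$N == cellKeys$N[k] & smp$D_target == cellKeys$D_target[k]
    v <- smp$rate_bits[sel]
    ci <- bootstrapCI(v, level = level, nBoot = nBoot,
                      seed = deriveSeed(seed, sprintf("boot_N%d_D%g",
                                                      cellKeys$N[k],
                                                      cellKeys$D_target[k])))
    data.frame(N = cellKeys$N[k], D_target = cellKeys$D_target[k],
               mean_rate_bits = mean(v), ci_low = ci[["low"]],
               ci_high = ci[["high"]], mean_beta = mean(smp$beta[sel]),
               n_samples = sum(sel))
  })
  cells <- do.call(rbind, cellRows)
  cells <- cells[order(cells$D_target, cells$N), , drop = FALSE]
  rownames(cells) <- NULL
  new("EnsembleSummary", family = family, shift = shift,
      samples = smp, cells = cells, seed = as.integer(seed),
      config = list(mode = mode, nPoints = nPoints, level = level,
                    nBoot = nBoot, maxIter = maxIter, tol = tol,
                    dTolFrac = dTolFrac, scaleParams = scaleParams,
                    Nlist = Nlist, Dtargets = Dtargets,
                    nSamples = nSamples))
}

#' @rdname accessors
#' @export
setMethod("cells", "EnsembleSummary", function(object) object@cells)

#' @rdname accessors
#' @export
setMethod("samples", "EnsembleSummary", function(object) object@samples)

#' Scaling of rate with environmental complexity
#'
#' Unweighted least-squares slope of the mean rate against \eqn{\log_2 N}
#' at one target distortion. In the high-fidelity regime the slope lies in
#' the bracket \eqn{[1 - D/d_{\min},\; 1 - D/\langle d \rangle]} up to its
#' standard error; in the low-fidelity regime it tends to 0 as N grows.
#' Weighting by the bootstrap variance is available for unequal-noise cells.
#'
#' @param summary an \linkS4class{EnsembleSummary}.
#' @param Dtarget which target distortion to fit (must match a cell).
#' @param weighted weight cells by inverse squared CI width?
#' @return named numeric: \code{slope}, \code{stderr}.
#' @export
regimeSlope <- function(summary, Dtarget, weighted = FALSE) {
  stopifnot(is(summary, "EnsembleSummary"))
  cl <- summary@cells
  cl <- cl[abs(cl$D_target - Dtarget) < 1e-12, , drop = FALSE]
  if (nrow(cl) < 3L)
    stop("insufficient data: regimeSlope needs at least 3 environment sizes")
  w <- if (weighted) 1 / pmax(cl$ci_high - cl$ci_low, 1e-12)^2 else NULL
  fit <- stats::lm(mean_rate_bits ~ log2(N), data = cl, weights = w)
  sm <- stats::summary.lm(fit)$coefficients
  c(slope = unname(sm["log2(N)", "Estimate"]),
    stderr = unname(sm["log2(N)", "Std. Error"]))
}
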