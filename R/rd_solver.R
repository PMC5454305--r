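#' Uniform codebook
#'
#' The maximally noisy codebook, \eqn{p(\hat x | x) = 1/N}; the fixed-point
#' iteration is initialized here for every beta.
#'
#' @param n number of states.
#' @return a \linkS4class{Codebook}.
#' @export
uniformCodebook <- function(n) {
  new("Codebook", conditional = matrix(1 / n, n, n), marginal = rep(1 / n, n))
}

#' @rdname accessors
#' @export
setMethod("conditional", "Codebook", function(object) object@conditional)

#' @rdname accessors
#' @export
setMethod("outputMarginal", "Codebook", function(object) object@marginal)

#' Rate of a codebook in bits
#'
#' Mutual information \eqn{I(X; \hat X) = H[\hat X] - H[\hat X | X]} in
#' bits, the resource cost of the perceptual channel. Terms with zero
#' probability contribute zero.
#'
#' @param cb a \linkS4class{Codebook}.
#' @param p a \linkS4class{SourceDistribution}.
#' @return rate in bits (non-negative).
#' @examples
#' rateOf(uniformCodebook(4), uniformSource(4))   # 0: percept independent of state
#' @export
rateOf <- function(cb, p) {
  q <- cb@conditional
  px <- probs(p)
  r <- as.vector(px %*% q)
  hxhat <- -sum(ifelse(r > 0, r * log2(r), 0))
  ql <- ifelse(q > 0, q * log2(q), 0)
  hcond <- -sum(px * rowSums(ql))
  max(0, hxhat - hcond)
}

#' Expected distortion of a codebook
#'
#' \eqn{D = \sum_x \sum_{\hat x} p(x)\, p(\hat x|x)\, d(x, \hat x)}: the
#' long-run average cost per perceived symbol.
#'
#' @param cb a \linkS4class{Codebook}.
#' @param d a \linkS4class{DistortionMatrix}.
#' @param p a \linkS4class{SourceDistribution}.
#' @return expected distortion (same units as the matrix).
#' @export
distortionOf <- function(cb, d, p) {
  sum(probs(p) * rowSums(cb@conditional * d@costs))
}

# Lagrangian tracked by the iteration: rate in nats + beta * distortion.
# This is the alternating-minimization objective that the exp(-beta*d)
# update descends, so it is the right convergence monitor.
.lagrangian <- function(cb, d, beta, p) {
  rateOf(cb, p) * log(2) + beta * distortionOf(cb, d, p)
}

#' One Blahut-Arimoto update
#'
#' Reweights each row of the codebook by \eqn{r(\hat x) e^{-\beta d(x, \hat x)}},
#' renormalizes, and recomputes the output marginal. Each full step can only
#' decrease the Lagrangian objective (rate plus \eqn{\beta} times
#' distortion); iterating to the fixed point yields the optimal codebook at
#' gain \eqn{\beta}. Weights are formed in the log domain (per-row maximum
#' subtracted before exponentiation) so gains of several hundred remain
#' stable.
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param beta non-negative gain.
#' @param cb current \linkS4class{Codebook}.
#' @param p a \linkS4class{SourceDistribution}.
#' @return the updated \linkS4class{Codebook}.
#' @export
baStep <- function(d, beta, cb, p) {
  stopifnot(beta >= 0)
  logr <- ifelse(cb@marginal > 0, log(cb@marginal), -Inf)
  logw <- matrix(logr, nrow = nStates(d), ncol = nStates(d), byrow = TRUE) -
    beta * d@costs
  mx <- logw[cbind(seq_len(nrow(logw)), max.col(logw, ties.method = "first"))]
  w <- exp(logw - mx)
  q <- w / rowSums(w)
  if (any(!is.finite(q)))
    stop("numerical failure: non-finite codebook entries in baStep")
  r <- as.vector(probs(p) %*% q)
  new("Codebook", conditional = q, marginal = r / sum(r))
}

#' Solve one rate-distortion point at fixed gain
#'
#' Iterates \code{\link{baStep}} from the uniform codebook until the
#' Lagrangian changes by less than \code{tol} or \code{maxIter} is reached
#' (the fixed-iteration mode of the original computation is recovered with
#' \code{tol = 0}). Returns the converged rate (bits), expected distortion,
#' iteration count and final objective.
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param beta non-negative gain.
#' @param p a \linkS4class{SourceDistribution}; defaults to uniform.
#' @param maxIter iteration cap (default 1000).
#' @param tol absolute tolerance on the Lagrangian change (default 1e-10).
#' @param keepCodebook keep the converged codebook in the result?
#' @return an \linkS4class{RDPoint}.
#' @examples
#' ham <- distortionMatrix(matrix(c(0, 1, 1, 0), 2))
#' solveRDPoint(ham, beta = log(3))   # distortion 1/4, rate 1 - Hb(1/4)
#' @export
solveRDPoint <- function(d, beta, p = uniformSource(nStates(d)),
                         maxIter = 1000L, tol = 1e-10,
                         keepCodebook = FALSE) {
  stopifnot(maxIter >= 1L, tol >= 0, beta >= 0)
  n <- nStates(d)
  px <- probs(p)
  # exp(-beta * d) is loop-invariant; with a zero diagonal each row keeps an
  # exact 1, so the plain-domain update cannot lose every entry of a row to
  # underflow unless the state's own percept has died (guarded below).
  E <- exp(-beta * d@costs)
  r <- rep(1 / n, n)
  q <- matrix(1 / n, n, n)
  # alternating-minimization objective via the per-row partition function:
  # L = -sum_x p(x) log Z_x, with Z_x = sum_xhat r(xhat) exp(-beta d(x, xhat));
  # equals rate (nats) + beta * distortion at the fixed point.
  lag <- Inf
  iters <- 0L
  converged <- FALSE
  for (i in seq_len(maxIter)) {
    w <- E * rep(r, each = n)
    z <- rowSums(w)
    if (any(z <= 0) || any(!is.finite(z))) {
      cb <- baStep(d, beta, new("Codebook", conditional = q, marginal = r), p)
      q <- cb@conditional
      r <- cb@marginal
      lag2 <- .lagrangian(cb, d, beta, p)
    } else {
      q <- w / z
      r <- as.vector(px %*% q)
      lag2 <- -sum(px * log(z))
    }
    iters <- i
    if (is.finite(lag) && abs(lag - lag2) < tol) {
      lag <- lag2
      converged <- TRUE
      break
    }
    lag <- lag2
  }
  cb <- new("Codebook", conditional = q, marginal = r / sum(r))
  new("RDPoint", beta = beta, rateBits = rateOf(cb, p),
      distortion = distortionOf(cb, d, p), iterations = iters,
      lagrangian = .lagrangian(cb, d, beta, p), converged = converged,
      codebook = if (keepCodebook) cb else NULL)
}

#' @rdname accessors
#' @export
setMethod("nEff", "RDPoint", function(object) 2^object@rateBits)

#' Solve for the codebook achieving a target distortion
#'
#' Bisection on the gain: \eqn{D_\beta} is monotone non-increasing in
#' \eqn{\beta}, so the bracket [0, betaHi] is grown by doubling until the
#' achieved distortion falls below the target (or below the absolute
#' distortion tolerance, for targets at or near zero), then bisected until
#' \eqn{|D_\beta - D^\ast| <} \code{dTolFrac * dMaxUseful} or the bracket
#' width falls below \code{betaTol}. Targets at or above the beta = 0
#' distortion return the beta = 0 (zero-rate) solution directly.
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param target target expected distortion (>= 0).
#' @param p a \linkS4class{SourceDistribution}; defaults to uniform.
#' @param maxIter,tol passed to \code{\link{solveRDPoint}}.
#' @param dTolFrac distortion tolerance as a fraction of the maximal useful
#'   distortion (default 1e-4).
#' @param betaTol minimal bracket width (default 1e-8).
#' @param betaMax cap on the bracket growth (default 2^20).
#' @return a list with \code{point} (the \linkS4class{RDPoint} closest to the
#'   target), \code{beta} (its gain) and \code{betaRequired} (the smallest
#'   bracketed gain whose solution has distortion <= target; \code{NA} if
#'   the target was met at beta = 0).
#' @export
solveAtDistortion <- function(d, target, p = uniformSource(nStates(d)),
                              maxIter = 1000L, tol = 1e-10,
                              dTolFrac = 1e-4, betaTol = 1e-8,
                              betaMax = 2^20) {
  stopifnot(target >= 0)
  dmax <- dMaxUseful(d, p)
  dTol <- dTolFrac * max(dmax, .Machine$double.eps)
  solve1 <- function(b) solveRDPoint(d, b, p, maxIter = maxIter, tol = tol)

  pt0 <- solve1(0)
  if (target >= pt0@distortion - dTol)
    return(list(point = pt0, beta = 0, betaRequired = NA_real_))

  lo <- 0; ptLo <- pt0
  hi <- 1; ptHi <- solve1(hi)
  while (ptHi@distortion > max(target, dTol) && hi < betaMax) {
    lo <- hi; ptLo <- ptHi
    hi <- hi * 2
    ptHi <- solve1(hi)
  }
  if (ptHi@distortion > target + dTol && ptHi@distortion > dTol)
    stop(sprintf(paste0("solver error: could not bracket target distortion ",
                        "%.6g (reached D = %.6g at beta = %.6g)"),
                 target, ptHi@distortion, hi))
  best <- ptHi
  while (hi - lo > betaTol) {
    if (abs(best@distortion - target) <= dTol) break
    mid <- (lo + hi) / 2
    ptMid <- solve1(mid)
    if (abs(ptMid@distortion - target) < abs(best@distortion - target))
      best <- ptMid
    if (ptMid@distortion > target) {
      lo <- mid; ptLo <- ptMid
    } else {
      hi <- mid; ptHi <- ptMid
    }
  }
  list(point = best, beta = best@beta,
       betaRequired = if (ptHi@distortion <= target + dTol) ptHi@beta
                      else best@beta)
}

#' Sweep a full rate-distortion curve
#'
#' Chooses gains so that the achieved distortions evenly tile the interval
#' from 0 to the maximal useful distortion (each interior target located by
#' bisection on beta), and closes the curve with the exact beta = 0
#' zero-rate point. A matrix with all-zero costs yields the single point
#' (R = 0, D = 0).
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param nPoints number of distortion targets (>= 2).
#' @param p a \linkS4class{SourceDistribution}; defaults to uniform.
#' @param maxIter,tol,dTolFrac,betaTol,betaMax solver settings, see
#'   \code{\link{solveAtDistortion}}.
#' @return an \linkS4class{RDCurve}.
#' @examples
#' ham <- distortionMatrix(matrix(c(0, 1, 1, 0), 2))
#' curvePoints(sweepCurve(ham, nPoints = 5))
#' @export
sweepCurve <- function(d, nPoints = 15L, p = uniformSource(nStates(d)),
                       maxIter = 1000L, tol = 1e-10, dTolFrac = 1e-4,
                       betaTol = 1e-8, betaMax = 2^20) {
  stopifnot(nPoints >= 2L)
  dmax <- dMaxUseful(d, p)
  asRow <- function(pt) data.frame(beta = pt@beta, rate_bits = pt@rateBits,
                                   distortion = pt@distortion,
                                   iterations = pt@iterations,
                                   lagrangian = pt@lagrangian)
  if (dmax <= .Machine$double.eps) {
    pts <- data.frame(beta = 0, rate_bits = 0, distortion = 0,
                      iterations = 0L, lagrangian = 0)
    return(new("RDCurve", points = pts, envRef = matrixHash(d)))
  }
  targets <- seq(0, dmax, length.out = nPoints)
  rows <- lapply(targets[-nPoints], function(tg) {
    asRow(solveAtDistortion(d, tg, p, maxIter = maxIter, tol = tol,
                            dTolFrac = dTolFrac, betaTol = betaTol,
                            betaMax = betaMax)$point)
  })
  # zero-rate endpoint: beta = 0 exactly (rate 0, distortion = uniform-codebook mean)
  rows <- c(rows, list(asRow(solveRDPoint(d, 0, p, maxIter = maxIter, tol = tol))))
  pts <- do.call(rbind, rows)
  pts <- pts[order(pts$distortion, -pts$rate_bits), , drop = FALSE]
  rownames(pts) <- NULL
  new("RDCurve", points = pts, envRef = matrixHash(d))
}

#' @rdname accessors
#' @export
setMethod("curvePoints", "RDCurve", function(object) object@points)
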