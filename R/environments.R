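#' Build an EnvironmentSpec
#'
#' Constructs a validated \linkS4class{EnvironmentSpec}. Shifted exponential
#' and lognormal families model unstructured environments where some
#' confusions cost much more than others; the shift sets the lower edge of
#' the off-diagonal support, i.e. the minimal confound of the ensemble
#' (typically 0, 1 or 20). \code{"correlated_exponential"} first draws the
#' shifted exponential matrix, then applies \code{\link{correlateMatrix}}.
#'
#' @param family \code{"exponential"}, \code{"lognormal"} or
#'   \code{"correlated_exponential"}.
#' @param shift non-negative support shift (distortion units).
#' @param scaleParams list: \code{mean} (exponential mean above the shift)
#'   or \code{meanlog}/\code{sdlog} (lognormal parameters).
#' @param nStates number of environmental states N (>= 2).
#' @param seed integer RNG seed; the spec plus seed reproduces a
#'   bit-identical matrix.
#' @return an \linkS4class{EnvironmentSpec}.
#' @examples
#' environmentSpec("exponential", shift = 1, nStates = 50, seed = 7)
#' @export
environmentSpec <- function(family = c("exponential", "lognormal",
                                       "correlated_exponential"),
                            shift = 0,
                            scaleParams = NULL,
                            nStates,
                            seed) {
  family <- match.arg(family)
  if (is.null(scaleParams)) {
    scaleParams <- if (family == "lognormal") list(meanlog = 0, sdlog = 1)
                   else list(mean = 1)
  }
  new("EnvironmentSpec", family = family, shift = as.numeric(shift),
      scaleParams = scaleParams, nStates = as.integer(nStates),
      seed = as.integer(seed))
}

#' Wrap a plain matrix as a DistortionMatrix
#'
#' @param costs square numeric matrix with zero diagonal, rows = true state,
#'   columns = percept.
#' @param spec optional generating \linkS4class{EnvironmentSpec}.
#' @param metadata optional provenance list.
#' @return a \linkS4class{DistortionMatrix}.
#' @examples
#' distortionMatrix(matrix(c(0, 1, 1, 0), 2))
#' @export
distortionMatrix <- function(costs, spec = NULL, metadata = list()) {
  new("DistortionMatrix", costs = unname(as.matrix(costs)), spec = spec,
      metadata = metadata)
}

#' Uniform source over N states
#'
#' The analysis takes \eqn{p(x) = 1/N}; its entropy \eqn{\log_2 N} is the
#' measure of environmental complexity.
#'
#' @param n number of states.
#' @return a \linkS4class{SourceDistribution}.
#' @export
uniformSource <- function(n) {
  new("SourceDistribution", probs = rep(1 / n, n))
}

#' @rdname accessors
#' @export
setMethod("probs", "SourceDistribution", function(object) object@probs)

#' @rdname accessors
#' @export
setMethod("entropyBits", "SourceDistribution", function(object) {
  p <- object@probs[object@probs > 0]
  -sum(p * log2(p))
})

#' @rdname accessors
#' @export
setMethod("nStates", "DistortionMatrix", function(object) nrow(object@costs))

#' @rdname accessors
#' @export
setMethod("nStates", "EnvironmentSpec", function(object) object@nStates)

#' @rdname accessors
#' @export
setMethod("nStates", "SourceDistribution", function(object) length(object@probs))

#' @rdname accessors
#' @export
setMethod("costs", "DistortionMatrix", function(object) object@costs)

.offDiag <- function(m) m[row(m) != col(m)]

#' @rdname accessors
#' @export
setMethod("dMin", "DistortionMatrix", function(object) min(.offDiag(object@costs)))

#' @rdname minimalConfound
#' @export
setMethod("minimalConfound", "DistortionMatrix", function(object) dMin(object))

#' @rdname accessors
#' @export
setMethod("meanOffDiag", "DistortionMatrix",
          function(object) mean(.offDiag(object@costs)))

#' @rdname dMaxUseful
#' @export
setMethod("dMaxUseful", "DistortionMatrix", function(object, p) {
  if (missing(p)) p <- uniformSource(nStates(object))
  stopifnot(nStates(p) == nStates(object))
  min(as.vector(probs(p) %*% object@costs))
})

#' Derive a task-specific seed from a root seed
#'
#' All randomness in a run flows from one root seed through this map, so the
#' order in which tasks execute cannot change any result. The derived seed
#' is a deterministic 31-bit function of the root seed, a task label and an
#' index.
#'
#' @param root integer root seed.
#' @param task character label of the task.
#' @param index non-negative integer (e.g. sample number).
#' @return an integer seed in [0, 2^31).
#' @export
deriveSeed <- function(root, task, index = 0L) {
  ch <- utf8ToInt(task)
  h <- sum(ch * seq_along(ch)) %% 1000003
  as.integer((as.double(root) %% 2147483629 * 48271 + h * 1009 + index) %%
             2147483629)
}

#' Draw a random distortion matrix
#'
#' Fills the \eqn{N(N-1)} off-diagonal entries with i.i.d. draws from the
#' spec's shifted family and sets the diagonal to zero. Deterministic given
#' the spec (the spec's seed scopes the RNG; the caller's RNG state is left
#' untouched). For the \code{"correlated_exponential"} family the shifted
#' exponential draw is followed by the pairwise-averaging step of
#' \code{\link{correlateMatrix}} under a derived seed.
#'
#' @param spec an \linkS4class{EnvironmentSpec}.
#' @return a \linkS4class{DistortionMatrix} carrying the spec.
#' @examples
#' dm <- drawMatrix(environmentSpec("exponential", shift = 1, nStates = 20,
#'                                  seed = 1))
#' dMin(dm) >= 1
#' @export
drawMatrix <- function(spec) {
  stopifnot(is(spec, "EnvironmentSpec"))
  validObject(spec)
  n <- spec@nStates
  m <- n * (n - 1L)
  draws <- withr::with_seed(spec@seed, switch(spec@family,
    exponential            = stats::rexp(m, rate = 1 / spec@scaleParams$mean),
    correlated_exponential = stats::rexp(m, rate = 1 / spec@scaleParams$mean),
    lognormal              = stats::rlnorm(m, meanlog = spec@scaleParams$meanlog,
                                           sdlog = spec@scaleParams$sdlog)
  ))
  d <- matrix(0, n, n)
  d[row(d) != col(d)] <- spec@shift + draws
  dm <- distortionMatrix(d, spec = spec)
  if (spec@family == "correlated_exponential")
    dm <- correlateMatrix(dm, seed = deriveSeed(spec@seed, "correlate"))
  dm
}

#' Introduce pairwise correlations between distortion entries
#'
#' Each off-diagonal entry is replaced by the average of itself and one
#' other off-diagonal entry chosen uniformly at random (never itself,
#' partners drawn with replacement). The diagonal stays zero, every output
#' entry stays at or above the input's minimal confound, and the ensemble
#' mean is preserved in expectation. The chosen partner indices are recorded
#' in \code{metadata$pairings} (positions within the column-major
#' off-diagonal vector).
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param seed integer seed for the pairing draw.
#' @return a \linkS4class{DistortionMatrix} with pairwise-correlated entries.
#' @export
correlateMatrix <- function(d, seed) {
  stopifnot(is(d, "DistortionMatrix"))
  m0 <- d@costs
  off <- row(m0) != col(m0)
  v <- m0[off]
  k <- length(v)
  partner <- withr::with_seed(as.integer(seed), sample.int(k - 1L, k, replace = TRUE))
  partner <- partner + (partner >= seq_len(k))  # skip self
  v2 <- (v + v[partner]) / 2
  m1 <- matrix(0, nrow(m0), ncol(m0))
  m1[off] <- v2
  meta <- d@metadata
  meta$pairings <- partner
  meta$correlated <- TRUE
  distortionMatrix(m1, spec = d@spec, metadata = meta)
}

#' Calibrate a lognormal ensemble to match a low-distortion quantile
#'
#' The heavy-tailed comparison ensemble is pinned to the exponential one by
#' a single quantile constraint: the probability of a confusion cheaper than
#' a small threshold must match, \eqn{P(d < D_0) = } \code{targetProb}.
#' With \code{logSd} fixed, the log-mean solves
#' \eqn{\Phi((\log D_0 - \mu)/\sigma) = } \code{targetProb}, i.e.
#' \eqn{\mu = \log D_0 - \sigma \Phi^{-1}(targetProb)}. The returned spec
#' has shift 0 (the calibration only makes sense on an unshifted support).
#'
#' @param targetProb probability in (0, 1).
#' @param targetDistortion threshold distortion \eqn{D_0 > 0}.
#' @param logSd lognormal log-sd (> 0); free parameter, default 1.
#' @param nStates,seed passed through to the spec.
#' @return an \linkS4class{EnvironmentSpec} with family \code{"lognormal"}
#'   whose CDF at \code{targetDistortion} equals \code{targetProb}.
#' @examples
#' sp <- calibrateLognormal(1 - exp(-0.001), 0.001, nStates = 50, seed = 1)
#' plnorm(0.001, sp@scaleParams$meanlog, sp@scaleParams$sdlog)
#' @export
calibrateLognormal <- function(targetProb, targetDistortion, logSd = 1,
                               nStates, seed) {
  if (!is.finite(targetProb) || targetProb <= 0 || targetProb >= 1)
    stop("calibration failure: targetProb must lie strictly in (0, 1)")
  if (!is.finite(targetDistortion) || targetDistortion <= 0)
    stop("calibration failure: targetDistortion must be > 0")
  if (!is.finite(logSd) || logSd <= 0)
    stop("calibration failure: logSd must be > 0")
  meanlog <- log(targetDistortion) - logSd * stats::qnorm(targetProb)
  if (!is.finite(meanlog)) stop("calibration failure: infeasible combination")
  environmentSpec("lognormal", shift = 0,
                  scaleParams = list(meanlog = meanlog, sdlog = logSd),
                  nStates = nStates, seed = seed)
}

#' Maximal useful distortion (function form)
#'
#' Convenience wrapper around the \code{\link{dMaxUseful}} accessor.
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param p a \linkS4class{SourceDistribution}; defaults to uniform.
#' @return a single number.
#' @export
maxUsefulDistortion <- function(d, p) {
  if (missing(p)) dMaxUseful(d) else dMaxUseful(d, p)
}

#' Content hash of a distortion matrix
#'
#' MD5 of a canonical full-precision text rendering of the costs; used in
#' manifests and as the environment reference of curves.
#'
#' @param d a \linkS4class{DistortionMatrix} or plain matrix.
#' @return a character hash.
#' @export
matrixHash <- function(d) {
  m <- if (is(d, "DistortionMatrix")) d@costs else as.matrix(d)
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(sprintf("%.17g", as.vector(m)), tf)
  unname(tools::md5sum(tf))
}
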