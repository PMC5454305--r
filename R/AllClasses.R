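#' @import methods
NULL

.ENSEMBLE_FAMILIES <- c("exponential", "lognormal", "correlated_exponential")

#' EnvironmentSpec: recipe for a random distortion matrix
#'
#' An \code{EnvironmentSpec} fully determines one random draw of an
#' \linkS4class{DistortionMatrix}: the ensemble family, the support shift
#' (the target minimal confound of the ensemble), the family-specific scale
#' parameters, the number of environmental states \eqn{N}, and the RNG seed.
#' A spec plus its seed reproduces a bit-identical matrix.
#'
#' @slot family character; one of \code{"exponential"}, \code{"lognormal"},
#'   \code{"correlated_exponential"}.
#' @slot shift non-negative numeric; lower edge of the off-diagonal support,
#'   so every confusion costs at least \code{shift}.
#' @slot scaleParams named list; \code{mean} for the (shifted) exponential
#'   families, \code{meanlog} and \code{sdlog} for the lognormal family.
#' @slot nStates integer \eqn{N \ge 2}; number of environmental states.
#' @slot seed integer RNG seed.
#' @seealso \code{\link{environmentSpec}}, \code{\link{drawMatrix}}
#' @export
setClass("EnvironmentSpec",
  slots = c(
    family      = "character",
    shift       = "numeric",
    scaleParams = "list",
    nStates     = "integer",
    seed        = "integer"
  )
)

setValidity("EnvironmentSpec", function(object) {
  msgs <- character()
  if (length(object@family) != 1L || !object@family %in% .ENSEMBLE_FAMILIES)
    msgs <- c(msgs, sprintf("family must be one of: %s",
                            paste(.ENSEMBLE_FAMILIES, collapse = ", ")))
  if (length(object@shift) != 1L || !is.finite(object@shift) || object@shift < 0)
    msgs <- c(msgs, "shift must be a single non-negative finite number")
  if (length(object@nStates) != 1L || is.na(object@nStates) || object@nStates < 2L)
    msgs <- c(msgs, "nStates must be an integer >= 2")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (length(object@family) == 1L && object@family %in% .ENSEMBLE_FAMILIES) {
    sp <- object@scaleParams
    if (object@family %in% c("exponential", "correlated_exponential")) {
      if (is.null(sp$mean) || !is.finite(sp$mean) || sp$mean <= 0)
        msgs <- c(msgs, "exponential families need scaleParams$mean > 0")
    } else {
      if (is.null(sp$meanlog) || !is.finite(sp$meanlog))
        msgs <- c(msgs, "lognormal family needs finite scaleParams$meanlog")
      if (is.null(sp$sdlog) || !is.finite(sp$sdlog) || sp$sdlog <= 0)
        msgs <- c(msgs, "lognormal family needs scaleParams$sdlog > 0")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' DistortionMatrix: the environment as a confusion-cost table
#'
#' An \eqn{N \times N} matrix of non-negative distortions \eqn{d(x, \hat x)},
#' the cost an organism pays for perceiving true state \eqn{x} (rows) as
#' percept \eqn{\hat x} (columns). The distortion is "normal":
#' \eqn{d(x, x) = 0} exactly. Summary statistics are exposed through
#' accessors: \code{\link{dMin}} (the minimal confound, the smallest
#' off-diagonal entry), \code{\link{meanOffDiag}} (the mean off-diagonal
#' distortion \eqn{\langle d \rangle}), and \code{\link{dMaxUseful}} (the
#' distortion of the best rate-zero codebook, the right endpoint of the
#' useful distortion axis).
#'
#' @slot costs numeric matrix; the distortions, rows = true state, columns =
#'   percept.
#' @slot spec the generating \linkS4class{EnvironmentSpec}, or \code{NULL}
#'   for matrices built directly from numbers.
#' @slot metadata list; provenance extras (e.g. the recorded pairings of
#'   \code{\link{correlateMatrix}}).
#' @seealso \code{\link{drawMatrix}}, \code{\link{distortionMatrix}}
#' @export
setClass("DistortionMatrix",
  slots = c(costs = "matrix", spec = "ANY", metadata = "list")
)

setValidity("DistortionMatrix", function(object) {
  d <- object@costs
  if (!is.numeric(d)) return("costs must be numeric")
  if (nrow(d) != ncol(d)) return("costs must be square")
  if (nrow(d) < 2L) return("need at least 2 states")
  if (any(!is.finite(d))) return("costs must be finite")
  if (any(d < 0)) return("costs must be non-negative")
  if (any(diag(d) != 0)) return("diagonal must be exactly zero (normal distortion)")
  TRUE
})

#' SourceDistribution: distribution over environmental states
#'
#' Probabilities \eqn{p(x)} over the \eqn{N} states. The analysis assumes a
#' uniform source, \eqn{p(x) = 1/N}, whose entropy \eqn{H[X] = \log_2 N}
#' serves as the measure of environmental complexity; non-uniform sources
#' are accepted by the solver but not by the ensemble machinery.
#'
#' @slot probs numeric vector summing to 1.
#' @seealso \code{\link{uniformSource}}, \code{\link{entropyBits}}
#' @export
setClass("SourceDistribution", slots = c(probs = "numeric"))

setValidity("SourceDistribution", function(object) {
  p <- object@probs
  if (length(p) < 2L) return("need at least 2 states")
  if (any(!is.finite(p)) || any(p < 0)) return("probabilities must be finite and >= 0")
  if (abs(sum(p) - 1) > 1e-9) return("probabilities must sum to 1")
  TRUE
})

#' Codebook: stochastic mapping from states to percepts
#'
#' The conditional distribution \eqn{p(\hat x \mid x)} (rows indexed by the
#' true state) together with its output marginal \eqn{r(\hat x)}. This is
#' the object the Blahut-Arimoto iteration optimizes.
#'
#' @slot conditional numeric matrix, each row a probability distribution.
#' @slot marginal numeric vector; the output marginal.
#' @seealso \code{\link{baStep}}, \code{\link{uniformCodebook}}
#' @export
setClass("Codebook", slots = c(conditional = "matrix", marginal = "numeric"))

setValidity("Codebook", function(object) {
  q <- object@conditional
  if (!is.numeric(q) || nrow(q) != ncol(q)) return("conditional must be a square numeric matrix")
  if (any(!is.finite(q)) || any(q < 0)) return("conditional entries must be finite and >= 0")
  if (max(abs(rowSums(q) - 1)) > 1e-8) return("each conditional row must sum to 1")
  if (length(object@marginal) != ncol(q)) return("marginal length must match conditional")
  if (abs(sum(object@marginal) - 1) > 1e-8) return("marginal must sum to 1")
  TRUE
})

#' RDPoint: one point on a rate-distortion curve
#'
#' The converged solution at one value of the gain \eqn{\beta}: the rate
#' \eqn{R_\beta} (mutual information, bits), the expected distortion
#' \eqn{D_\beta}, the number of fixed-point iterations used, and the final
#' Lagrangian objective (rate in nats plus \eqn{\beta} times distortion).
#' \code{\link{nEff}} returns \eqn{2^{R}}, the effective number of stored
#' states.
#'
#' @slot beta non-negative numeric; the gain / inverse temperature.
#' @slot rateBits numeric in \eqn{[0, \log_2 N]}.
#' @slot distortion non-negative numeric.
#' @slot iterations integer; iterations performed.
#' @slot lagrangian numeric; final objective value.
#' @slot converged logical; whether the tolerance was met before the
#'   iteration cap.
#' @slot codebook the converged \linkS4class{Codebook}, or \code{NULL} if
#'   dropped to save space.
#' @seealso \code{\link{solveRDPoint}}, \code{\link{solveAtDistortion}}
#' @export
setClass("RDPoint",
  slots = c(
    beta = "numeric", rateBits = "numeric", distortion = "numeric",
    iterations = "integer", lagrangian = "numeric", converged = "logical",
    codebook = "ANY"
  )
)

setValidity("RDPoint", function(object) {
  if (object@beta < 0) return("beta must be >= 0")
  if (object@rateBits < -1e-9) return("rate must be >= 0")
  if (object@distortion < -1e-12) return("distortion must be >= 0")
  TRUE
})

#' RDCurve: a swept rate-distortion function
#'
#' A set of \linkS4class{RDPoint}s whose distortions tile the interval from
#' 0 to the maximal useful distortion, stored as a data frame sorted by
#' distortion, plus a reference identifying the environment (a content hash
#' of the matrix). Along the curve the rate is non-increasing in distortion
#' and the point set is convex up to numerical tolerance.
#'
#' @slot points data.frame with columns \code{beta}, \code{rate_bits},
#'   \code{distortion}, \code{iterations}, \code{lagrangian}.
#' @slot envRef character; content hash of the distortion matrix (and the
#'   generating spec when known).
#' @seealso \code{\link{sweepCurve}}, \code{\link{rateAtDistortion}}
#' @export
setClass("RDCurve", slots = c(points = "data.frame", envRef = "character"))

setValidity("RDCurve", function(object) {
  pts <- object@points
  need <- c("beta", "rate_bits", "distortion", "iterations", "lagrangian")
  if (!all(need %in% names(pts)))
    return(sprintf("points must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(pts) == 0L) return("curve must contain at least one point")
  if (is.unsorted(pts$distortion)) return("points must be sorted by distortion")
  if (any(diff(pts$rate_bits) > 1e-6))
    return("rate must be non-increasing in distortion (tolerance 1e-6)")
  TRUE
})

#' EnsembleSummary: rates across environment size and distortion targets
#'
#' The result of \code{\link{runEnsemble}}: per-sample solver results
#' (long format) and per-(N, D-target) cells aggregating the mean rate with
#' a percentile-bootstrap confidence interval, for one ensemble family and
#' shift. \code{\link{regimeSlope}} fits the growth of the mean rate with
#' environmental complexity \eqn{\log_2 N}.
#'
#' @slot family,shift the ensemble identity.
#' @slot samples data.frame, one row per (N, D-target, sample).
#' @slot cells data.frame, one row per (N, D-target) with \code{mean_rate_bits},
#'   \code{ci_low}, \code{ci_high}, \code{mean_beta}, \code{n_samples}.
#' @slot seed integer root seed of the run.
#' @slot config list; solver and bootstrap settings used.
#' @export
setClass("EnsembleSummary",
  slots = c(
    family = "character", shift = "numeric",
    samples = "data.frame", cells = "data.frame",
    seed = "integer", config = "list"
  )
)

setValidity("EnsembleSummary", function(object) {
  cl <- object@cells
  need <- c("N", "D_target", "mean_rate_bits", "ci_low", "ci_high", "n_samples")
  if (!all(need %in% names(cl)))
    return(sprintf("cells must have columns: %s", paste(need, collapse = ", ")))
  bad <- cl$ci_low > cl$mean_rate_bits + 1e-9 | cl$ci_high < cl$mean_rate_bits - 1e-9
  if (any(bad)) return("each cell must satisfy ci_low <= mean <= ci_high")
  if (any(cl$n_samples < 2L)) return("each cell needs n_samples >= 2")
  TRUE
})
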