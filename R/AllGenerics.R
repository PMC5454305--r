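#' Accessors for the core classes
#'
#' @param object a lossyRD object.
#' @name accessors
NULL

#' @describeIn accessors number of environmental states \eqn{N}.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @describeIn accessors the raw cost matrix.
#' @export
setGeneric("costs", function(object) standardGeneric("costs"))

#' @describeIn accessors minimal confound \eqn{d_{\min}}: the smallest
#'   off-diagonal distortion.
#' @export
setGeneric("dMin", function(object) standardGeneric("dMin"))

#' @describeIn accessors mean off-diagonal distortion \eqn{\langle d \rangle}.
#' @export
setGeneric("meanOffDiag", function(object) standardGeneric("meanOffDiag"))

#' Maximal useful distortion
#'
#' Distortion of the best rate-zero codebook: the minimum over percepts
#' \eqn{\hat x} of \eqn{\sum_x p(x) d(x, \hat x)}. Beyond this value R(D) is
#' identically zero, so it is the right endpoint when tiling the distortion
#' axis. It never exceeds the mean of all \eqn{N^2} entries.
#'
#' @param object a \linkS4class{DistortionMatrix}.
#' @param p a \linkS4class{SourceDistribution}; defaults to uniform.
#' @return a single number.
#' @export
setGeneric("dMaxUseful", function(object, p) standardGeneric("dMaxUseful"))

#' @describeIn accessors source probabilities \eqn{p(x)}.
#' @export
setGeneric("probs", function(object) standardGeneric("probs"))

#' @describeIn accessors entropy in bits.
#' @export
setGeneric("entropyBits", function(object) standardGeneric("entropyBits"))

#' @describeIn accessors conditional distribution \eqn{p(\hat x | x)} of a
#'   codebook.
#' @export
setGeneric("conditional", function(object) standardGeneric("conditional"))

#' @describeIn accessors output marginal \eqn{r(\hat x)} of a codebook.
#' @export
setGeneric("outputMarginal", function(object) standardGeneric("outputMarginal"))

#' @describeIn accessors effective number of stored states \eqn{2^{R}}.
#' @export
setGeneric("nEff", function(object) standardGeneric("nEff"))

#' @describeIn accessors the point table of an \linkS4class{RDCurve} or the
#'   per-cell table of an \linkS4class{EnsembleSummary}.
#' @export
setGeneric("curvePoints", function(object) standardGeneric("curvePoints"))

#' @describeIn accessors aggregated (N, D-target) cells of an ensemble run.
#' @export
setGeneric("cells", function(object) standardGeneric("cells"))

#' @describeIn accessors per-sample results of an ensemble run.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' Minimal confound of an environment
#'
#' The smallest distortion that can arise from any miscoding of the true
#' state: the minimum over the off-diagonal entries of the cost matrix. It
#' separates the high-fidelity regime (target distortion below it; rate
#' grows as \eqn{\log_2 N}) from the low-fidelity regime (rate asymptotes
#' to a constant as N grows).
#'
#' @param object a \linkS4class{DistortionMatrix}.
#' @return a single number.
#' @examples
#' minimalConfound(distortionMatrix(matrix(c(0, 3, 2, 0), 2)))
#' @export
setGeneric("minimalConfound", function(object) standardGeneric("minimalConfound"))
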