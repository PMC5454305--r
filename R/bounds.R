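#' Binary entropy in bits
#'
#' \eqn{H_b(p) = -p \log_2 p - (1-p)\log_2(1-p)}, with \eqn{H_b(0) =
#' H_b(1) = 0}.
#'
#' @param p probability in [0, 1] (vectorized).
#' @return entropy in bits.
#' @export
binaryEntropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p == 0 | p == 1, 0,
         -p * log2(p) - (1 - p) * log2(1 - p))
}

#' Quantile upper bound on R(D)
#'
#' In a random environment, a state can be merged with every percept whose
#' confusion costs less than D; on average a fraction \eqn{P(d < D)} of
#' states qualify as such synonyms. Coding only down to that ambiguity level
#' needs at most \eqn{\log_2 (1 / P(d < D))} bits, independent of N — the
#' heart of the low-fidelity asymptote. The bound diverges as
#' \eqn{P \to 0}, i.e. as D approaches the minimal confound from above;
#' \code{cdfAtD = 0} returns \code{Inf} as an explicit regime marker.
#'
#' @param cdfAtD \eqn{P(d < D)} under the off-diagonal entry distribution,
#'   in [0, 1].
#' @return bits (possibly \code{Inf}).
#' @examples
#' quantileUpperBound(1 - exp(-0.01))    # about 6.65 bits
#' quantileUpperBound(1 - exp(-0.001))   # about 9.97 bits
#' @export
quantileUpperBound <- function(cdfAtD) {
  if (!is.finite(cdfAtD) || cdfAtD < 0 || cdfAtD > 1)
    stop("domain error: cdfAtD must lie in [0, 1]")
  if (cdfAtD == 0) return(Inf)
  log2(1 / cdfAtD)
}

#' Synonym-count upper bound on R(D)
#'
#' For a concrete matrix, \eqn{N_D(x)} counts the percepts that are
#' synonyms of x at tolerance D: those with \eqn{d(x, \hat x) < D}, the
#' state itself included (its cost is 0). Mapping each state uniformly onto
#' its synonym set gives rate \eqn{(1/N)\sum_x \log_2 (N / N_D(x))}, an
#' upper bound on the optimal rate.
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param D distortion tolerance (> 0).
#' @return bits.
#' @examples
#' m <- distortionMatrix(matrix(c(0, 3, 1, 0), 2))
#' synonymUpperBound(m, 2)   # 0.5 bits
#' @export
synonymUpperBound <- function(d, D) {
  stopifnot(is(d, "DistortionMatrix"))
  if (!is.finite(D) || D <= 0) stop("domain error: D must be > 0")
  n <- nStates(d)
  nd <- rowSums(d@costs < D)
  mean(log2(n / nd))
}

#' Uniform-allocation upper bound (explicit sub-optimal codebook)
#'
#' The codebook that keeps probability 1 - C on the correct percept and
#' spreads C equally over the other N - 1 percepts has rate
#' \eqn{\log_2 N - H_b(C) - C \log_2(N-1)} and expected distortion
#' \eqn{C \langle d \rangle}; as an achievable point it upper-bounds the
#' rate-distortion function at that distortion.
#'
#' @param N number of states (>= 2).
#' @param C total off-diagonal probability, in [0, 1].
#' @param meanOffDiag mean off-diagonal distortion \eqn{\langle d \rangle}.
#' @return list with \code{rate_bits} and \code{distortion}.
#' @examples
#' uniformAllocBound(4, 0.25, 1)   # rate about 0.792 bits, distortion 0.25
#' @export
uniformAllocBound <- function(N, C, meanOffDiag) {
  if (!is.finite(C) || C < 0 || C > 1) stop("domain error: C must lie in [0, 1]")
  stopifnot(N >= 2)
  rate <- log2(N) - binaryEntropy(C) - C * log2(N - 1)
  list(rate_bits = max(0, rate), distortion = C * meanOffDiag)
}

#' Rate-distortion function of the uniform (least-stringent) environment
#'
#' If every confusion cost the same penalty \eqn{d_{\min}}, the environment
#' would be a Hamming-type source with known rate-distortion function
#' \eqn{\log_2 N - H_b(D/d_{\min}) - (D/d_{\min})\log_2(N-1)} for
#' \eqn{D \le d_{\min}(N-1)/N}, and 0 beyond. Since every real confusion
#' costs at least \eqn{d_{\min}}, this is a lower bound on the true R(D) —
#' the dashed comparison line of the high-fidelity regime.
#'
#' @param N number of states (>= 2).
#' @param D target distortion (>= 0).
#' @param dMin minimal confound (> 0).
#' @return bits.
#' @examples
#' uniformEnvRD(2, 0.25, 1)   # 1 - Hb(0.25), about 0.1887 bits
#' @export
uniformEnvRD <- function(N, D, dMin) {
  stopifnot(N >= 2, D >= 0)
  if (!is.finite(dMin) || dMin <= 0)
    stop("domain error: dMin must be > 0 (bound undefined otherwise)")
  frac <- D / dMin
  if (frac >= (N - 1) / N) return(0)
  max(0, log2(N) - binaryEntropy(frac) - frac * log2(N - 1))
}

#' Large-N bracket on the high-fidelity rate
#'
#' Leading-order forms of the uniform-environment lower bound and the
#' uniform-allocation upper bound: for \eqn{D < d_{\min}} the optimal rate
#' lies between \eqn{(1 - D/d_{\min})\log_2 N} and
#' \eqn{(1 - D/\langle d \rangle)\log_2 N} up to O(1) corrections, so the
#' rate grows linearly in environmental complexity \eqn{\log_2 N}.
#'
#' @param N number of states.
#' @param D target distortion, must satisfy \eqn{0 \le D < d_{\min}}.
#' @param dMin minimal confound.
#' @param meanOffDiag mean off-diagonal distortion, \eqn{\ge d_{\min}}.
#' @return list with \code{lo_bits} and \code{hi_bits}.
#' @examples
#' asymptoticBounds(1024, 0.5, 1, 2)   # lo 5, hi 7.5 bits
#' @export
asymptoticBounds <- function(N, D, dMin, meanOffDiag) {
  stopifnot(N >= 2, D >= 0, dMin <= meanOffDiag)
  if (D >= dMin)
    stop("regime error: asymptotic bracket applies to the high-fidelity regime (D < dMin)")
  list(lo_bits = (1 - D / dMin) * log2(N),
       hi_bits = (1 - D / meanOffDiag) * log2(N))
}

#' Gain required for high-fidelity coding to pay off
#'
#' A non-coding organism has rate 0 and distortion about
#' \eqn{\langle d \rangle}; a high-fidelity codebook with distortion D and
#' rate \eqn{C \log_2 N} outperforms it only when the gain satisfies
#' \eqn{\beta \ge (C / (\langle d \rangle - D)) \log_2 N} — so the required
#' gain grows linearly with environmental complexity.
#'
#' @param C rate constant (> 0), bits per \eqn{\log_2 N}.
#' @param meanOffDiag mean off-diagonal distortion \eqn{\langle d \rangle}.
#' @param D achieved distortion, must be < \code{meanOffDiag}.
#' @param N number of states.
#' @return the threshold gain.
#' @examples
#' requiredGain(1, 2, 1, 4)   # 2
#' @export
requiredGain <- function(C, meanOffDiag, D, N) {
  stopifnot(C > 0, N >= 2)
  if (!(D < meanOffDiag))
    stop("domain error: D must be below the mean off-diagonal distortion")
  (C / (meanOffDiag - D)) * log2(N)
}

#' Gaussian source, squared-error distortion
#'
#' The continuum analogue: for a Gaussian signal of variance \eqn{\sigma^2}
#' under mean-squared error, \eqn{R(D) = \tfrac12 \log_2(\sigma^2 / D)} for
#' \eqn{D < \sigma^2} and 0 otherwise. The rate is monotone increasing in
#' \eqn{\sigma^2} at fixed D, so a continuous environment has no
#' low-fidelity regime.
#'
#' @param sigma2 signal variance (> 0).
#' @param D target mean-squared error (> 0).
#' @return bits.
#' @examples
#' gaussianRD(2, 0.5)   # 1 bit
#' @export
gaussianRD <- function(sigma2, D) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("domain error: sigma2 must be > 0")
  if (!is.finite(D) || D <= 0) stop("domain error: D must be > 0")
  if (D >= sigma2) return(0)
  0.5 * log2(sigma2 / D)
}

#' All bounds for one matrix at one distortion
#'
#' Evaluates every closed-form bound at distortion D for a concrete matrix,
#' using the empirical off-diagonal CDF for the quantile bound and C =
#' D / \eqn{\langle d \rangle} for the uniform-allocation bound, and labels
#' the regime (high fidelity if D < minimal confound, else low fidelity).
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param D distortion (> 0).
#' @param path optional path; when given, the report is also written as JSON.
#' @return a list with the bound values and the regime label.
#' @export
boundsReport <- function(d, D, path = NULL) {
  stopifnot(is(d, "DistortionMatrix"), D > 0)
  n <- nStates(d)
  off <- .offDiag(d@costs)
  md <- mean(off)
  dmin <- min(off)
  alloc <- if (D <= md) uniformAllocBound(n, D / md, md)$rate_bits else 0
  rep <- list(
    N = n,
    D = D,
    d_min = dmin,
    mean_off_diag = md,
    regime = if (D < dmin) "high-fidelity" else "low-fidelity",
    quantile_ub = quantileUpperBound(mean(off < D)),
    synonym_ub = synonymUpperBound(d, D),
    uniform_alloc_ub = alloc,
    uniform_env_lb = if (dmin > 0) uniformEnvRD(n, D, dmin) else NA_real_,
    required_beta = if (D < md) requiredGain(1, md, D, n) else NA_real_
  )
  if (D < dmin) {
    ab <- asymptoticBounds(n, D, dmin, md)
    rep$asym_lo <- ab$lo_bits
    rep$asym_hi <- ab$hi_bits
  }
  if (!is.null(path))
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rep
}
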