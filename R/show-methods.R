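setMethod("show", "EnvironmentSpec", function(object) {
  sp <- vapply(object@scaleParams, function(x) format(x, digits = 4), "")
  cat(sprintf("EnvironmentSpec: %s ensemble, N = %d\n", object@family,
              object@nStates))
  cat(sprintf("  shift (target d_min): %g | %s | seed %d\n", object@shift,
              paste(names(sp), sp, sep = " = ", collapse = ", "),
              object@seed))
})

setMethod("show", "DistortionMatrix", function(object) {
  cat(sprintf("DistortionMatrix: %d states\n", nStates(object)))
  cat(sprintf("  minimal confound d_min = %.4g | <d> = %.4g | d_max_useful = %.4g\n",
              dMin(object), meanOffDiag(object), dMaxUseful(object)))
  if (!is.null(object@spec))
    cat(sprintf("  drawn from %s ensemble (shift %g, seed %d)\n",
                object@spec@family, object@spec@shift, object@spec@seed))
  if (isTRUE(object@metadata$correlated))
    cat("  pairwise-correlated entries\n")
})

setMethod("show", "SourceDistribution", function(object) {
  cat(sprintf("SourceDistribution over %d states, H[X] = %.4g bits\n",
              nStates(object), entropyBits(object)))
})

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: %d states -> %d percepts\n",
              nrow(object@conditional), ncol(object@conditional)))
  cat(sprintf("  mean diagonal (correct-percept) probability: %.4g\n",
              mean(diag(object@conditional))))
})

setMethod("show", "RDPoint", function(object) {
  cat(sprintf("RDPoint: beta = %.6g\n", object@beta))
  cat(sprintf("  rate = %.6g bits (N_eff = %.4g) | distortion = %.6g\n",
              object@rateBits, nEff(object), object@distortion))
  cat(sprintf("  %d iterations (%s), Lagrangian = %.6g\n", object@iterations,
              if (object@converged) "converged" else "iteration cap",
              object@lagrangian))
})

setMethod("show", "RDCurve", function(object) {
  pts <- object@points
  cat(sprintf("RDCurve: %d points, distortion span [%.4g, %.4g], rate span [%.4g, %.4g] bits\n",
              nrow(pts), min(pts$distortion), max(pts$distortion),
              min(pts$rate_bits), max(pts$rate_bits)))
  cat(sprintf("  environment: %s\n", object@envRef))
})

setMethod("show", "EnsembleSummary", function(object) {
  cat(sprintf("EnsembleSummary: %s ensemble, shift %g, root seed %d\n",
              object@family, object@shift, object@seed))
  cat(sprintf("  N in {%s}; D targets {%s}; %d samples per N\n",
              paste(unique(object@cells$N), collapse = ", "),
              paste(unique(object@cells$D_target), collapse = ", "),
              max(object@cells$n_samples)))
  print(object@cells, digits = 4)
})
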