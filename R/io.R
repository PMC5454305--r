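#' Write / read a distortion matrix as CSV
#'
#' Matrices are stored as plain CSV, N rows by N columns, no header, rows =
#' true state, columns = percept; when the matrix carries a generating spec,
#' a sidecar JSON (\code{<path>.json}) records family, shift, scale
#' parameters, N and seed so the draw can be reproduced bit-identically.
#'
#' @param d a \linkS4class{DistortionMatrix}.
#' @param path CSV output path.
#' @return \code{writeDistortionMatrix}: the path, invisibly;
#'   \code{readDistortionMatrix}: a \linkS4class{DistortionMatrix}.
#' @export
writeDistortionMatrix <- function(d, path) {
  stopifnot(is(d, "DistortionMatrix"))
  utils::write.table(format(d@costs, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (!is.null(d@spec)) {
    sp <- d@spec
    jsonlite::write_json(
      list(family = sp@family, shift = sp@shift,
           scale_params = sp@scaleParams, n_states = sp@nStates,
           seed = sp@seed),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writeDistortionMatrix
#' @export
readDistortionMatrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  spec <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    spec <- environmentSpec(sj$family, shift = sj$shift,
                            scaleParams = as.list(sj$scale_params),
                            nStates = sj$n_states, seed = sj$seed)
  }
  distortionMatrix(m, spec = spec)
}

#' Write / read a swept curve as CSV
#'
#' Curves are stored as CSV with header
#' \code{beta,rate_bits,distortion,iterations}; a sidecar JSON records the
#' solver configuration used and the matrix content hash.
#'
#' @param curve an \linkS4class{RDCurve}.
#' @param path CSV output path.
#' @param solverConfig optional list of solver settings for the sidecar.
#' @return \code{writeRDCurve}: the path, invisibly; \code{readRDCurve}: an
#'   \linkS4class{RDCurve}.
#' @export
writeRDCurve <- function(curve, path, solverConfig = list()) {
  stopifnot(is(curve, "RDCurve"))
  pts <- curve@points[, c("beta", "rate_bits", "distortion", "iterations")]
  utils::write.csv(format(pts, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(matrix_hash = curve@envRef,
                            solver_config = solverConfig),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRDCurve
#' @export
readRDCurve <- function(path) {
  pts <- utils::read.csv(path)
  pts$lagrangian <- NA_real_
  envRef <- "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    envRef <- jsonlite::read_json(sidecar)$matrix_hash
  pts <- pts[order(pts$distortion, -pts$rate_bits), , drop = FALSE]
  rownames(pts) <- NULL
  new("RDCurve", points = pts, envRef = as.character(envRef))
}

#' Write an ensemble summary as tidy CSV plus manifest
#'
#' Writes \code{ensemble.csv} (columns family, shift, N, D_target,
#' mean_rate_bits, ci_low, ci_high, n_samples), \code{samples.csv} (the
#' per-draw long table) and a manifest recording the config, the root seed,
#' every per-sample seed and a content hash per matrix; a rerun from the
#' same config and seed reproduces the CSV bytes exactly.
#'
#' @param summary an \linkS4class{EnsembleSummary}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeEnsembleSummary <- function(summary, dir) {
  stopifnot(is(summary, "EnsembleSummary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cl <- summary@cells
  out <- data.frame(family = summary@family, shift = summary@shift,
                    N = cl$N, D_target = cl$D_target,
                    mean_rate_bits = cl$mean_rate_bits,
                    ci_low = cl$ci_low, ci_high = cl$ci_high,
                    n_samples = cl$n_samples)
  utils::write.csv(format(out, digits = 17, trim = TRUE),
                   file.path(dir, "ensemble.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(format(summary@samples, digits = 17, trim = TRUE),
                   file.path(dir, "samples.csv"), row.names = FALSE,
                   quote = FALSE)
  smp <- summary@samples
  key <- sprintf("%s_N%d_sample%d", smp$family, smp$N, smp$sample)
  dedup <- !duplicated(key)
  writeManifest(dir,
                config = c(summary@config,
                           list(family = summary@family, shift = summary@shift)),
                seeds = c(list(root = summary@seed),
                          stats::setNames(as.list(smp$seed[dedup]), key[dedup])),
                hashes = stats::setNames(as.list(smp$matrix_hash[dedup]),
                                         key[dedup]))
  invisible(dir)
}
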