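#' Default run configuration
#'
#' The full set of tunable settings for a pipeline run: solver (iteration
#' cap, Lagrangian tolerance, bisection tolerances), ensemble (families,
#' shifts, sizes, distortion targets, sample counts, bootstrap resamples),
#' the root seed and the output directory. A config round-trips losslessly
#' through its JSON representation.
#'
#' @return a named list.
#' @export
defaultRunConfig <- function() {
  list(
    solver = list(max_iter = 1000L, tol = 1e-10, d_tol_frac = 1e-4,
                  beta_tol = 1e-8, beta_max = 2^20),
    ensemble = list(family = "exponential", shift = 1, scale_mean = 1,
                    N_list = c(20L, 50L, 100L), D_targets = c(0.5, 1.5),
                    n_samples = 10L, n_boot = 1000L, level = 0.68,
                    mode = "target", n_points = 15L),
    seed = 1L,
    out_dir = "results"
  )
}

.mergeConfig <- function(defaults, given, path = "") {
  if (!is.list(given))
    stop(sprintf("config error: '%s' must be an object", path))
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop(sprintf("config error: unknown key%s %s",
                 if (length(unknown) > 1) "s" else "",
                 paste(sprintf("'%s%s'", path, unknown), collapse = ", ")))
  for (k in names(given)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- .mergeConfig(defaults[[k]], given[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- given[[k]]
    }
  }
  defaults
}

.validateConfig <- function(cfg) {
  s <- cfg$solver
  if (s$max_iter < 1L) stop("config error: 'solver.max_iter' must be >= 1")
  if (s$tol < 0) stop("config error: 'solver.tol' must be >= 0")
  e <- cfg$ensemble
  if (e$n_samples < 2L) stop("config error: 'ensemble.n_samples' must be >= 2")
  if (any(e$D_targets <= 0)) stop("config error: 'ensemble.D_targets' must be > 0")
  if (!e$family %in% .ENSEMBLE_FAMILIES)
    stop("config error: 'ensemble.family' not recognized")
  cfg
}

#' Load a run configuration from JSON
#'
#' Reads a JSON config, fills unspecified settings with the defaults of
#' \code{\link{defaultRunConfig}}, and rejects unknown keys by name. An
#' empty object yields all defaults.
#'
#' @param path JSON file path.
#' @return a validated config list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config error: no such file '%s'", path))
  given <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(given) == 0L) given <- list()
  cfg <- .mergeConfig(defaultRunConfig(), given)
  # JSON has one number type; restore the documented storage modes
  cfg$seed <- as.integer(cfg$seed)
  cfg$solver$max_iter <- as.integer(cfg$solver$max_iter)
  for (k in c("tol", "d_tol_frac", "beta_tol", "beta_max"))
    cfg$solver[[k]] <- as.numeric(cfg$solver[[k]])
  cfg$ensemble$N_list <- as.integer(cfg$ensemble$N_list)
  cfg$ensemble$n_samples <- as.integer(cfg$ensemble$n_samples)
  cfg$ensemble$n_boot <- as.integer(cfg$ensemble$n_boot)
  cfg$ensemble$n_points <- as.integer(cfg$ensemble$n_points)
  for (k in c("shift", "scale_mean", "D_targets", "level"))
    cfg$ensemble[[k]] <- as.numeric(cfg$ensemble[[k]])
  .validateConfig(cfg)
}

#' Write a run configuration as JSON
#'
#' @param config a config list.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records everything needed to regenerate a results directory bit for bit:
#' the exact config, the root seed, every derived seed, and a content hash
#' per generated matrix.
#'
#' @param resultsDir directory the results live in (created if needed).
#' @param config the config list used.
#' @param seeds named list/vector of seeds in effect.
#' @param hashes named list/vector of matrix content hashes.
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(resultsDir, config, seeds, hashes) {
  if (!dir.exists(resultsDir))
    dir.create(resultsDir, recursive = TRUE)
  path <- file.path(resultsDir, "manifest.json")
  jsonlite::write_json(
    list(package = "lossyRD",
         version = as.character(utils::packageVersion("lossyRD")),
         config = config, seeds = seeds, hashes = hashes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and validate a manifest
#'
#' @param path manifest file.
#' @return the manifest list; errors if the seed record is missing.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest error: no such file '%s'", path))
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(man$seeds) || length(man$seeds) == 0L)
    stop("manifest validation error: no seeds recorded, replay impossible")
  if (is.null(man$config))
    stop("manifest validation error: no config recorded")
  man
}

#' Log a message to standard error
#'
#' Level-filtered logging ("debug" < "info" < "warn"); messages about
#' stochastic steps should include the seed in effect.
#'
#' @param msg message (sprintf-style with \code{...}).
#' @param ... sprintf arguments.
#' @param level message level.
#' @param threshold minimum level to emit (set once per run).
#' @return invisibly, whether the message was emitted.
#' @export
logMsg <- function(msg, ..., level = c("info", "debug", "warn"),
                   threshold = getOption("lossyRD.logLevel", "info")) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  emit <- ranks[[level]] >= ranks[[threshold]]
  if (emit)
    message(sprintf("[%s] %s", toupper(level), sprintf(msg, ...)))
  invisible(emit)
}
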