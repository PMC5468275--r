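# Configuration object and the two end-to-end workflows: reaction
# free-energy mapping (samples -> surface/profile -> path -> barrier) and
# head-separation free-energy difference (two pulling ensembles ->
# Jarzynski estimates -> delta-delta-G).  Every run writes a manifest JSON
# recording the resolved configuration, its hash and all output files, and
# reruns with the same seed/config are byte-identical.

#' Build an analysis configuration
#'
#' All settings of the pipeline in one validated, serializable object.
#' Numerics are stored as doubles so that the JSON round trip
#' (\code{\link{writeAnalysisConfig}} / \code{\link{readAnalysisConfig}})
#' reproduces the object exactly.
#'
#' @param temperature temperature (K); default 300.
#' @param seed RNG seed.
#' @param gridBins bins per axis (48 for 2D surfaces, 100 for 1D profiles).
#' @param loessSpan,loessDegree LOESS smoothing parameters.
#' @param bootstrapReplicates bootstrap replicates (default 100).
#' @param connectivity path connectivity, 4 or 8.
#' @param prominence transition-state prominence threshold (kcal/mol).
#' @param occupancyCutoff distance cutoff for occupancy analyses (Angstrom).
#' @param ... further named settings (e.g. \code{samplesFile},
#'   \code{nSamples}, \code{nTraj}, \code{wellDepthDelta}); all stored
#'   verbatim.
#' @return an \linkS4class{AnalysisConfig}.
#' @export
analysisConfig <- function(temperature = 300, seed = 1, gridBins = 100,
                           loessSpan = 0.25, loessDegree = 2,
                           bootstrapReplicates = 100, connectivity = 8,
                           prominence = 0.5, occupancyCutoff = 3.5, ...) {
  values <- list(temperature = as.numeric(temperature), seed = as.numeric(seed),
                 gridBins = as.numeric(gridBins), loessSpan = as.numeric(loessSpan),
                 loessDegree = as.numeric(loessDegree),
                 bootstrapReplicates = as.numeric(bootstrapReplicates),
                 connectivity = as.numeric(connectivity),
                 prominence = as.numeric(prominence),
                 occupancyCutoff = as.numeric(occupancyCutoff))
  extra <- list(...)
  for (nm in names(extra))
    values[[nm]] <- if (is.numeric(extra[[nm]])) as.numeric(extra[[nm]]) else extra[[nm]]
  new("AnalysisConfig", values = values)
}

#' Read a configuration setting
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @param name setting name.
#' @param default value returned when the setting is absent.
#' @export
configValue <- function(config, name, default = NULL) {
  if (name %in% names(config@values)) config@values[[name]] else default
}

#' Serialize / deserialize a configuration
#'
#' JSON round trip; \code{readAnalysisConfig(writeAnalysisConfig(x, p))}
#' is \code{identical} to \code{x}.
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @param path JSON file path.
#' @export
writeAnalysisConfig <- function(config, path) {
  stopifnot(is(config, "AnalysisConfig"))
  jsonlite::write_json(config@values, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAnalysisConfig
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  values <- jsonlite::read_json(path, simplifyVector = TRUE)
  # whole numbers come back as integers; the config stores doubles
  values <- lapply(values, function(v) if (is.integer(v)) as.numeric(v) else v)
  new("AnalysisConfig", values = values)
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; recorded in every output
#' header and manifest so results can be traced to the exact settings.
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeAnalysisConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

.manifest <- function(config, outDir, files, extra = list()) {
  man <- c(list(tool = "felscape",
                version = as.character(utils::packageVersion("felscape")),
                config = config@values, config_hash = configHash(config),
                files = lapply(files, basename)), extra)
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the reaction free-energy workflow
#'
#' Chains sample input -> free-energy estimation (-> bootstrap errors) ->
#' minimum-energy path -> barrier report, and writes TSV outputs plus a
#' manifest JSON with full provenance (config, hash, seed, version).
#'
#' Input samples come from \code{samplesFile} in the config if set
#' (an energy-sample TSV); otherwise a synthetic ground-truth table is
#' generated: Boltzmann samples of a 1D double well
#' (\code{doubleWellHeight}, default 3 kcal/mol) or, with
#' \code{dimension = 2}, of the Mueller-Brown landscape.
#'
#' @param config an \linkS4class{AnalysisConfig}.
#' @param outDir output directory (created if needed).
#' @return list with the estimated object(s), barrier (kcal/mol) and the
#'   manifest path.
#' @export
runReactionWorkflow <- function(config, outDir) {
  stopifnot(is(config, "AnalysisConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  hdr <- sprintf("# config %s", hash)
  temperature <- configValue(config, "temperature", 300)
  seed <- as.integer(configValue(config, "seed", 1))
  smooth <- loessParams(configValue(config, "loessSpan", 0.25),
                        configValue(config, "loessDegree", 2))
  reps <- configValue(config, "bootstrapReplicates", 100)
  samplesFile <- configValue(config, "samplesFile")
  if (!is.null(samplesFile)) {
    if (!file.exists(samplesFile))
      stop("samples file not found: ", samplesFile, call. = FALSE)
    table <- readEnergySamples(samplesFile)
  } else {
    dim2 <- identical(configValue(config, "dimension", 1), 2)
    spec <- if (dim2) muellerBrownPotential()
            else doubleWellPotential(height = configValue(config, "doubleWellHeight", 3))
    table <- boltzmannSamples(spec, temperature = temperature,
                              n = configValue(config, "nSamples", 2e5),
                              seed = seed,
                              stepSd = configValue(config, "stepSd", 0.1))
  }
  d <- ncol(rcValues(table))
  grid <- defaultGrid(table, bins = configValue(config, "gridBins"))
  files <- list()
  if (d == 2L) {
    obj <- if (reps >= 2)
      bootstrapSurface(table, grid, temperature, smooth, replicates = reps, seed = seed)
    else estimateFes2d(table, grid, temperature, smooth)
    files$surface <- file.path(outDir, "surface.tsv")
    writeSurface(obj, files$surface, hdr)
    minima <- findMinima(obj, configValue(config, "connectivity", 8))
    if (nrow(minima@nodes) < 2)
      stop("reaction workflow: fewer than two basins on the surface", call. = FALSE)
    mep <- minimumEnergyPath(obj, minima@nodes[1, ], minima@nodes[2, ],
                             connectivity = configValue(config, "connectivity", 8),
                             prominence = configValue(config, "prominence", 0.5))
    files$path <- file.path(outDir, "path.tsv")
    writePath(mep, files$path, hdr)
    barrier <- mep@barrier
    result <- list(surface = obj, path = mep, barrier = barrier)
  } else {
    obj <- if (reps >= 2)
      bootstrapSurface(table, grid, temperature, smooth, replicates = reps, seed = seed)
    else estimateProfile1d(table, grid, temperature, smooth)
    files$profile <- file.path(outDir, "profile.tsv")
    writeProfile(obj, files$profile, hdr)
    wells <- profileBarrier(obj)
    barrier <- wells$barrier
    result <- list(profile = obj, wells = wells,
                   ts = locateTransitionStates(obj, configValue(config, "prominence", 0.5)),
                   barrier = barrier)
  }
  man <- .manifest(config, outDir, files,
                   extra = list(barrier_kcal_mol = barrier, seed = seed))
  c(result, list(manifest = man))
}

#' Run the head-separation free-energy difference workflow
#'
#' Estimates the Jarzynski free-energy profile for two pulling-trace
#' ensembles (condition A and condition B) and reports the
#' \eqn{\Delta\Delta G} profile and its value at the final common
#' displacement, with bootstrap CIs when each ensemble has at least two
#' trajectories.
#'
#' Trace ensembles come from \code{tracesA}/\code{tracesB} in the config
#' (character vectors of trace TSV paths); otherwise synthetic ensembles
#' are pulled on two harmonic potentials whose stiffness differs so that
#' the conditions differ by a known, configurable free-energy gap.
#'
#' @inheritParams runReactionWorkflow
#' @return list with both \linkS4class{JarzynskiResult}s, the comparison
#'   and the manifest path.
#' @export
runSeparationWorkflow <- function(config, outDir) {
  stopifnot(is(config, "AnalysisConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(config)
  hdr <- sprintf("# config %s", hash)
  temperature <- configValue(config, "temperature", 300)
  seed <- as.integer(configValue(config, "seed", 1))
  loadEnsemble <- function(paths) lapply(paths, readSMDTrace)
  tracesA <- configValue(config, "tracesA")
  if (!is.null(tracesA)) {
    ensA <- loadEnsemble(tracesA)
    ensB <- loadEnsemble(configValue(config, "tracesB"))
  } else {
    nTraj <- as.integer(configValue(config, "nTraj", 5))
    kA <- configValue(config, "springWellA", 2)
    kB <- configValue(config, "springWellB", 1)
    pull <- function(k, seedOff) lapply(seq_len(nTraj), function(i) {
      simulateSMD(harmonicPotential(k = k, center = 0),
                  thermostatParams(temperature = temperature, friction = 20,
                                   timeStep = 0.005, seed = seed + seedOff + i,
                                   steps = 1L),
                  spring = configValue(config, "spring", 200),
                  startCenter = 0, velocity = configValue(config, "velocity", 1.5),
                  duration = configValue(config, "duration", 1),
                  hold = configValue(config, "hold", 0.01), stride = 10L)
    })
    ensA <- pull(kA, 0L)
    ensB <- pull(kB, 1000L)
  }
  worksA <- lapply(ensA, accumulateWork)
  worksB <- lapply(ensB, accumulateWork)
  reps <- configValue(config, "bootstrapReplicates", 100)
  estimate <- function(w, seedOff) {
    if (length(w) >= 2 && reps >= 2)
      jarzynskiBootstrap(w, temperature, replicates = reps, seed = seed + seedOff)
    else jarzynskiEstimate(w, temperature)
  }
  resA <- estimate(worksA, 1L)
  resB <- estimate(worksB, 2L)
  # compare on the shorter of the two grids
  ncomm <- min(length(resA@displacement), length(resB@displacement))
  trim <- function(r, n) new("JarzynskiResult",
    displacement = r@displacement[seq_len(n)], dg = r@dg[seq_len(n)],
    ciLow = r@ciLow[seq_len(n)], ciHigh = r@ciHigh[seq_len(n)],
    nTraj = r@nTraj, temperature = r@temperature)
  cmp <- compareConditions(trim(resA, ncomm), trim(resB, ncomm))
  files <- list(a = file.path(outDir, "jarzynski_A.tsv"),
                b = file.path(outDir, "jarzynski_B.tsv"))
  writeJarzynski(resA, files$a, hdr)
  writeJarzynski(resB, files$b, hdr)
  man <- .manifest(config, outDir, files,
                   extra = list(ddg_final_kcal_mol = cmp$final, seed = seed,
                                ci_available = length(worksA) >= 2 && reps >= 2))
  list(conditionA = resA, conditionB = resB, comparison = cmp, manifest = man)
}
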