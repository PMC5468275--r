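# Plain-text I/O: TSV payloads with '#' comment headers and JSON sidecars
# for metadata.  Readers skip comment lines, so every writer may prepend a
# provenance header (tool version, config hash).

.headerLines <- function(extra = character()) {
  c(sprintf("# felscape %s", as.character(utils::packageVersion("felscape"))), extra)
}

.writeTsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLines(comments), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, comment.char = "#", sep = "\t", header = TRUE,
             check.names = FALSE)
}

#' Write / read an energy-sample table
#'
#' TSV with header \code{rc1_angstrom[<tab>rc2_angstrom]<tab>energy_kcal_mol}.
#'
#' @param table an \linkS4class{EnergySampleTable}.
#' @param path output file.
#' @param comments extra '#' header lines.
#' @return the path (write) or an \linkS4class{EnergySampleTable} (read).
#' @export
writeEnergySamples <- function(table, path, comments = character()) {
  stopifnot(is(table, "EnergySampleTable"))
  rc <- rcValues(table)
  df <- as.data.frame(rc)
  names(df) <- paste0(colnames(rc), "_angstrom")
  df$energy_kcal_mol <- sampleEnergies(table)
  .writeTsv(df, path, comments)
}

#' @rdname writeEnergySamples
#' @export
readEnergySamples <- function(path) {
  df <- .readTsv(path)
  rcCols <- grep("^rc[12]_angstrom$", names(df), value = TRUE)
  if (!length(rcCols) || !"energy_kcal_mol" %in% names(df))
    stop("not an energy-sample TSV: ", path, call. = FALSE)
  rc <- as.matrix(df[rcCols])
  colnames(rc) <- sub("_angstrom$", "", rcCols)
  new("EnergySampleTable", rc = rc, energy = df$energy_kcal_mol)
}

#' Write / read a steered-pulling trace
#'
#' TSV \code{time_ns<tab>rc_angstrom<tab>center_angstrom} plus a JSON
#' sidecar (\code{<path>.json}) holding the protocol: spring constant,
#' velocity and hold/ramp durations.
#'
#' @param trace an \linkS4class{SMDTrace}.
#' @inheritParams writeEnergySamples
#' @export
writeSMDTrace <- function(trace, path, comments = character()) {
  stopifnot(is(trace, "SMDTrace"))
  df <- data.frame(time_ns = trace@times, rc_angstrom = trace@coord,
                   center_angstrom = trace@center)
  .writeTsv(df, path, comments)
  meta <- list(spring_kcal_mol_A2 = trace@spring, velocity_A_ns = trace@velocity,
               hold_ns = trace@holdDuration, ramp_ns = trace@rampDuration)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSMDTrace
#' @export
readSMDTrace <- function(path) {
  df <- .readTsv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("SMDTrace", times = df$time_ns, coord = df$rc_angstrom,
      center = df$center_angstrom, spring = meta$spring_kcal_mol_A2,
      velocity = meta$velocity_A_ns, holdDuration = meta$hold_ns,
      rampDuration = meta$ramp_ns)
}

#' Write a free-energy surface
#'
#' One TSV row per occupied bin:
#' \code{bin_i bin_j rc1_center rc2_center dg_raw dg_smooth occupancy sd_boot},
#' plus a JSON sidecar with grid, temperature and out-of-range count.
#'
#' @param surface a \linkS4class{FreeEnergySurface}.
#' @inheritParams writeEnergySamples
#' @export
writeSurface <- function(surface, path, comments = character()) {
  stopifnot(is(surface, "FreeEnergySurface"))
  occIdx <- which(is.finite(surface@raw))
  ij <- arrayInd(occIdx, surface@grid@bins)
  sdb <- if (length(surface@bootstrapSD)) surface@bootstrapSD[occIdx] else NA_real_
  df <- data.frame(bin_i = ij[, 1], bin_j = ij[, 2],
                   rc1_center = binCenters(surface@grid, 1)[ij[, 1]],
                   rc2_center = binCenters(surface@grid, 2)[ij[, 2]],
                   dg_raw = surface@raw[occIdx], dg_smooth = surface@smoothed[occIdx],
                   occupancy = surface@occupancy[occIdx], sd_boot = sdb)
  .writeTsv(df, path, comments)
  meta <- list(lower = surface@grid@lower, upper = surface@grid@upper,
               bins = surface@grid@bins, temperature_K = surface@temperature,
               out_of_range = surface@outOfRange)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname writeSurface
#' @export
readSurface <- function(path) {
  df <- .readTsv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- gridSpec(meta$lower, meta$upper, meta$bins)
  nb <- grid@bins
  raw <- sm <- occ <- matrix(NA_real_, nb[1], nb[2])
  lin <- df$bin_i + (df$bin_j - 1L) * nb[1]
  raw[lin] <- df$dg_raw; sm[lin] <- df$dg_smooth
  occM <- matrix(0, nb[1], nb[2]); occM[lin] <- df$occupancy
  sdM <- matrix(numeric(0), 0, 0)
  if (any(!is.na(df$sd_boot))) {
    sdM <- matrix(NA_real_, nb[1], nb[2]); sdM[lin] <- df$sd_boot
  }
  new("FreeEnergySurface", grid = grid, raw = raw, smoothed = sm,
      occupancy = occM, temperature = meta$temperature_K, bootstrapSD = sdM,
      outOfRange = as.integer(meta$out_of_range))
}

#' Write a free-energy profile
#'
#' TSV \code{bin_i rc_center dg_raw dg_smooth occupancy sd_boot}.
#'
#' @param profile a \linkS4class{FreeEnergyProfile}.
#' @inheritParams writeEnergySamples
#' @export
writeProfile <- function(profile, path, comments = character()) {
  stopifnot(is(profile, "FreeEnergyProfile"))
  n <- length(profile@centers)
  df <- data.frame(bin_i = seq_len(n), rc_center = profile@centers,
                   dg_raw = if (length(profile@raw)) profile@raw else NA_real_,
                   dg_smooth = profile@dg,
                   occupancy = if (length(profile@occupancy)) profile@occupancy else NA_real_,
                   sd_boot = if (length(profile@bootstrapSD)) profile@bootstrapSD else NA_real_)
  .writeTsv(df, path, comments)
  meta <- list(temperature_K = profile@temperature)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a path result
#'
#' TSV \code{step bin_i bin_j arc_angstrom dg_kcal_mol is_ts} plus a JSON
#' summary (barrier, S/P nodes, transition states).
#'
#' @param path_result a \linkS4class{PathResult}.
#' @inheritParams writeEnergySamples
#' @export
writePath <- function(path_result, path, comments = character()) {
  stopifnot(is(path_result, "PathResult"))
  k <- nrow(path_result@nodes)
  isTs <- integer(k)
  isTs[path_result@tsIntermediate] <- 1L
  isTs[path_result@tsMain] <- 2L
  df <- data.frame(step = seq_len(k), bin_i = path_result@nodes[, 1],
                   bin_j = path_result@nodes[, 2], arc_angstrom = path_result@arc,
                   dg_kcal_mol = path_result@dg, is_ts = isTs)
  .writeTsv(df, path, comments)
  meta <- list(barrier_kcal_mol = path_result@barrier,
               s_node = path_result@nodes[1, ], p_node = path_result@nodes[k, ],
               ts_main = path_result@tsMain,
               ts_intermediate = path_result@tsIntermediate,
               connectivity = path_result@connectivity)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Write a Jarzynski result
#'
#' TSV \code{displacement_angstrom dg_kcal_mol ci_lo ci_hi n_traj}.
#'
#' @param result a \linkS4class{JarzynskiResult}.
#' @inheritParams writeEnergySamples
#' @export
writeJarzynski <- function(result, path, comments = character()) {
  stopifnot(is(result, "JarzynskiResult"))
  df <- data.frame(displacement_angstrom = result@displacement,
                   dg_kcal_mol = result@dg, ci_lo = result@ciLow,
                   ci_hi = result@ciHigh, n_traj = result@nTraj)
  .writeTsv(df, path, comments)
  invisible(path)
}

#' @rdname writeJarzynski
#' @export
readJarzynski <- function(path) {
  df <- .readTsv(path)
  new("JarzynskiResult", displacement = df$displacement_angstrom,
      dg = df$dg_kcal_mol, ciLow = df$ci_lo, ciHigh = df$ci_hi,
      nTraj = as.integer(df$n_traj[1]), temperature = NA_real_)
}
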