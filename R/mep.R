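# Minimum-energy path extraction on gridded free-energy surfaces.
#
# The path criterion is minimax (lowest highest point) - the chemically
# meaningful quantity for a rate-limiting barrier and equivalent, for
# barrier heights, to node-by-node flooding.  Among all minimax-optimal
# paths the one with the smallest summed node free energy is returned
# (secondary Dijkstra on the admissible sub-grid), with a deterministic
# lexicographic preference when that is still tied.  Missing (unoccupied)
# bins are impassable.

# extract the value matrix and bin-center coordinates from a surface or a
# plain matrix (plain matrices use unit-width bins: handy in tests)
.surfaceValues <- function(surface) {
  if (is(surface, "FreeEnergySurface")) {
    list(val = dgValues(surface),
         cx = binCenters(surface@grid, 1), cy = binCenters(surface@grid, 2))
  } else if (is.matrix(surface)) {
    list(val = surface, cx = seq_len(nrow(surface)), cy = seq_len(ncol(surface)))
  } else stop("surface must be a FreeEnergySurface or a matrix", call. = FALSE)
}

.neighbourOffsets <- function(connectivity) {
  if (connectivity == 4L) cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else rbind(cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L)),
             cbind(c(-1L, -1L, 1L, 1L), c(-1L, 1L, -1L, 1L)))
}

#' Local minima of a gridded surface
#'
#' A node is a local minimum when no neighbour (under the chosen
#' connectivity) has a strictly lower value; missing bins are impassable
#' and never count as neighbours.  A flat plateau with no lower neighbour
#' is reported once, at its lexicographically lowest node.
#'
#' @param surface a \linkS4class{FreeEnergySurface} or a numeric matrix
#'   (NA = missing bin).
#' @param connectivity 4 or 8 (default; diagonal moves allowed).
#' @return a \linkS4class{MinimaSet}, ordered by increasing free energy.
#' @export
findMinima <- function(surface, connectivity = 8L) {
  connectivity <- as.integer(connectivity)
  stopifnot(connectivity %in% c(4L, 8L))
  sv <- .surfaceValues(surface)
  val <- sv$val
  nr <- nrow(val); nc <- ncol(val)
  if (!any(is.finite(val))) stop("surface has no occupied bins", call. = FALSE)
  off <- .neighbourOffsets(connectivity)
  # group equal-value plateaus by flood fill, then test the whole component
  comp <- matrix(0L, nr, nc)
  ncomp <- 0L
  nodes <- list(); dgs <- numeric()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!is.finite(val[i, j]) || comp[i, j] != 0L) next
    ncomp <- ncomp + 1L
    v <- val[i, j]
    queue <- matrix(c(i, j), ncol = 2)
    comp[i, j] <- ncomp
    members <- queue
    isMin <- TRUE
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(off))) {
        ni <- cur[1] + off[k, 1]; nj <- cur[2] + off[k, 2]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        nv <- val[ni, nj]
        if (!is.finite(nv)) next
        if (nv < v) { isMin <- FALSE; next }
        if (nv == v && comp[ni, nj] == 0L) {
          comp[ni, nj] <- ncomp
          queue <- rbind(queue, c(ni, nj))
          members <- rbind(members, c(ni, nj))
        }
      }
    }
    if (isMin) {
      ordm <- order(members[, 1], members[, 2])
      nodes[[length(nodes) + 1L]] <- members[ordm[1], ]
      dgs <- c(dgs, v)
    }
  }
  ord <- order(dgs)
  new("MinimaSet", nodes = do.call(rbind, nodes)[ord, , drop = FALSE], dg = dgs[ord])
}

# Dijkstra with either minimax (path cost = max node value) or additive
# (sum of node values) metric, on the finite cells of `val` optionally
# masked to `admissible`.  O(n^2) node selection: ample for <= ~100x100.
.gridDijkstra <- function(val, start, end, off, metric = c("minimax", "sum"),
                          admissible = NULL) {
  metric <- match.arg(metric)
  nr <- nrow(val); nc <- ncol(val); n <- nr * nc
  ok <- is.finite(val)
  if (!is.null(admissible)) ok <- ok & admissible
  lin <- function(ij) ij[1] + (ij[2] - 1L) * nr
  s <- lin(start); e <- lin(end)
  dist <- rep(Inf, n); pred <- rep(NA_integer_, n); done <- rep(FALSE, n)
  if (!ok[s] || !ok[e]) return(NULL)
  dist[s] <- val[s]
  repeat {
    u <- which.min(ifelse(done, Inf, dist))   # ties -> lowest linear index
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    if (u == e) break
    ui <- ((u - 1L) %% nr) + 1L; uj <- ((u - 1L) %/% nr) + 1L
    for (k in seq_len(nrow(off))) {
      ni <- ui + off[k, 1]; nj <- uj + off[k, 2]
      if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
      v <- ni + (nj - 1L) * nr
      if (done[v] || !ok[v]) next
      nd <- if (metric == "minimax") max(dist[u], val[v]) else dist[u] + val[v]
      if (nd < dist[v]) { dist[v] <- nd; pred[v] <- u }
    }
  }
  if (!is.finite(dist[e])) return(NULL)
  path <- e
  while (!is.na(pred[path[1]])) path <- c(pred[path[1]], path)
  cbind(((path - 1L) %% nr) + 1L, ((path - 1L) %/% nr) + 1L)
}

#' Minimum-energy path between two grid nodes
#'
#' Returns a path from \code{start} to \code{end} through occupied bins
#' that minimizes the maximum free energy along it; among minimax-optimal
#' paths, the one with the smallest summed node free energy.  The barrier
#' is the path maximum minus the value at the start node.  Transition
#' states along the path are located with \code{\link{locateTransitionStates}}.
#'
#' @inheritParams findMinima
#' @param start,end grid nodes \code{c(i, j)} (1-based).
#' @param prominence prominence threshold (kcal/mol) for intermediate
#'   transition states.
#' @return a \linkS4class{PathResult}.
#' @export
minimumEnergyPath <- function(surface, start, end, connectivity = 8L,
                              prominence = 0.5) {
  connectivity <- as.integer(connectivity)
  stopifnot(connectivity %in% c(4L, 8L))
  sv <- .surfaceValues(surface)
  val <- sv$val
  start <- as.integer(start); end <- as.integer(end)
  for (nd in list(start, end))
    if (length(nd) != 2L || any(nd < 1L) || nd[1] > nrow(val) || nd[2] > ncol(val) ||
        !is.finite(val[nd[1], nd[2]]))
      stop("start and end must be occupied grid nodes c(i, j)", call. = FALSE)
  off <- .neighbourOffsets(connectivity)
  p1 <- .gridDijkstra(val, start, end, off, "minimax")
  if (is.null(p1)) {
    finiteMax <- max(val[is.finite(val)])
    stop(sprintf(paste0("start and end are not connected through occupied bins ",
                        "(no path exists even at the maximum occupied level ",
                        "%.4g kcal/mol)"), finiteMax), call. = FALSE)
  }
  level <- max(val[p1])
  admissible <- is.finite(val) & (val <= level + 1e-12)
  p2 <- .gridDijkstra(val, start, end, off, "sum", admissible = admissible)
  nodes <- if (is.null(p2)) p1 else p2
  dg <- val[nodes]
  stepLen <- if (nrow(nodes) > 1) {
    dx <- sv$cx[nodes[-1, 1]] - sv$cx[nodes[-nrow(nodes), 1]]
    dy <- sv$cy[nodes[-1, 2]] - sv$cy[nodes[-nrow(nodes), 2]]
    sqrt(dx^2 + dy^2)
  } else numeric(0)
  arc <- c(0, cumsum(stepLen))
  ts <- locateTransitionStates(dg, prominence = prominence)
  new("PathResult", nodes = nodes, dg = dg, arc = arc,
      barrier = max(dg) - dg[1], tsMain = ts$main,
      tsIntermediate = ts$intermediate, connectivity = connectivity)
}

#' Free-energy profile along a path
#'
#' Arc length accumulates Euclidean bin-center distances; values are
#' re-referenced so the starting (S) node is 0.
#'
#' @param path a \linkS4class{PathResult}.
#' @return a \linkS4class{FreeEnergyProfile} over arc length.
#' @export
pathProfile <- function(path) {
  stopifnot(is(path, "PathResult"))
  new("FreeEnergyProfile", centers = path@arc, dg = path@dg - path@dg[1],
      raw = numeric(0), occupancy = numeric(0), temperature = NA_real_,
      bootstrapSD = numeric(0))
}

#' Locate transition states along a 1D profile
#'
#' The main transition state is the global maximum (lowest index on ties).
#' Intermediate transition states are the other strict interior local
#' maxima whose topographic prominence (height above the higher of the key
#' saddles separating the peak from higher terrain on each side) reaches
#' the threshold.  The default threshold, 0.5 kcal/mol, is of the order of
#' kB*T at 300 K.
#'
#' @param profile a \linkS4class{FreeEnergyProfile} or numeric vector of
#'   free energies along the path.
#' @param prominence prominence threshold (kcal/mol).
#' @return list with \code{main} (index) and \code{intermediate}
#'   (integer vector, possibly empty).
#' @export
locateTransitionStates <- function(profile, prominence = 0.5) {
  dg <- if (is(profile, "FreeEnergyProfile")) profile@dg else as.numeric(profile)
  n <- length(dg)
  main <- as.integer(which.max(dg))
  if (n < 3L) return(list(main = main, intermediate = integer(0)))
  peaks <- which(vapply(2:(n - 1), function(i)
    dg[i] > dg[i - 1] && dg[i] > dg[i + 1], logical(1))) + 1L
  prom <- vapply(peaks, function(i) {
    h <- dg[i]
    leftHigher <- which(dg[seq_len(i - 1)] > h)
    baseL <- if (length(leftHigher)) min(dg[(max(leftHigher) + 1):(i - 1)])
             else min(dg[seq_len(i - 1)])
    rightHigher <- which(dg[(i + 1):n] > h) + i
    baseR <- if (length(rightHigher)) min(dg[(i + 1):(min(rightHigher) - 1)])
             else min(dg[(i + 1):n])
    h - max(baseL, baseR)
  }, numeric(1))
  inter <- peaks[peaks != main & prom >= prominence]
  list(main = main, intermediate = as.integer(inter))
}

#' Barrier height from a profile
#'
#' \eqn{\Delta G^\ddag} = maximum of the profile at or after the starting
#' (substrate) index, minus the value at that index; always >= 0.
#'
#' @inheritParams locateTransitionStates
#' @param sIndex index of the starting basin (default 1).
#' @return barrier height (kcal/mol).
#' @export
barrierHeight <- function(profile, sIndex = 1L) {
  dg <- if (is(profile, "FreeEnergyProfile")) profile@dg else as.numeric(profile)
  sIndex <- as.integer(sIndex)
  if (sIndex < 1L || sIndex > length(dg)) stop("sIndex out of range", call. = FALSE)
  max(dg[sIndex:length(dg)]) - dg[sIndex]
}

#' Between-wells barrier of a 1D profile
#'
#' Locates the local minima of a profile (endpoints included), keeps the
#' two deepest, and returns the highest point of the profile between them
#' relative to the deeper one - the well-to-well reaction barrier, immune
#' to high-energy bins sampled beyond the wells.
#'
#' @inheritParams locateTransitionStates
#' @return list with \code{sIndex}, \code{pIndex} (indices of the two
#'   wells, S the deeper), \code{tsIndex} and \code{barrier} (kcal/mol).
#' @export
profileBarrier <- function(profile) {
  dg <- if (is(profile, "FreeEnergyProfile")) profile@dg else as.numeric(profile)
  n <- length(dg)
  if (n < 3L) stop("profile too short to hold two wells", call. = FALSE)
  isMin <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) dg[i - 1] else Inf
    right <- if (i < n) dg[i + 1] else Inf
    dg[i] < left && dg[i] < right
  }, logical(1))
  mins <- which(isMin)
  if (length(mins) < 2L) stop("profile has fewer than two wells", call. = FALSE)
  mins <- mins[order(dg[mins])][1:2]
  s <- mins[which.min(dg[mins])]
  p <- setdiff(mins, s)
  seg <- min(s, p):max(s, p)
  tsIdx <- seg[which.max(dg[seg])]
  list(sIndex = s, pIndex = p, tsIndex = tsIdx, barrier = dg[tsIdx] - dg[s])
}
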