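#' Region-of-influence mask around the implant
#'
#' A parallelepiped box (default 21.7 x 18.8 x 28.2 cm) centred on the
#' implant bounding box, within which the presence of the implant
#' materially alters the temperature field; safety metrics are reported
#' inside it. The box dimensions are configuration, not re-derived.
#'
#' @param model a \code{TissueModel} with an implant.
#' @param size box edge lengths (m) along x, y, z.
#' @return logical 3D mask (clipped to the grid); errors if the box fails
#'   to contain the implant bounding box.
#' @export
regionOfInfluence <- function(model, size = c(0.217, 0.188, 0.282)) {
  if (!any(model@implantMask)) stop("model has no implant")
  d <- dim(model@labels)
  ijk <- arrayInd(which(model@implantMask), d)
  lo <- apply(ijk, 2, min); hi <- apply(ijk, 2, max)
  # allow a one-voxel rasterisation slack before declaring the box too small
  if (any((hi - lo + 1L) * model@spacing > size + 1.5 * model@spacing))
    stop("region-of-influence box smaller than the implant bounding box")
  ctr <- (lo + hi) / 2
  half <- size / (2 * model@spacing)
  mask <- array(FALSE, d)
  rng <- lapply(1:3, function(a) {
    a0 <- min(ceiling(ctr[a] - half[a]), lo[a])
    a1 <- max(floor(ctr[a] + half[a]), hi[a])
    max(1L, a0):min(d[a], a1)
  })
  mask[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  mask
}

#' Maximum temperature increase (K)
#'
#' @param state a \code{ThermalState}.
#' @param mask optional logical mask restricting the maximum (e.g. the
#'   region of influence); must select at least one voxel.
#' @param snapshot snapshot index, default the last.
#' @export
maxDeltaT <- function(state, mask = NULL, snapshot = length(state@snapshots)) {
  u <- state@snapshots[[snapshot]]
  if (is.null(mask)) return(max(u))
  if (!any(mask)) stop("empty mask")
  max(u[mask])
}

#' Tissue mass above a temperature-increase threshold
#'
#' Mass (grams) of voxels whose temperature increase exceeds the threshold,
#' grouped by tissue, within a region. Implant voxels are excluded.
#'
#' @param state a \code{ThermalState}.
#' @param model the matching \code{TissueModel}.
#' @param threshold temperature-increase threshold (K), > 0.
#' @param region optional logical mask (default: whole grid).
#' @param snapshot snapshot index, default the last.
#' @return named numeric vector, grams per tissue (all tissues listed,
#'   zeros included), plus a "total" attribute-free sum entry named
#'   \code{total}.
#' @export
massAboveThreshold <- function(state, model, threshold, region = NULL,
                               snapshot = length(state@snapshots)) {
  stopifnot(threshold > 0)
  u <- state@snapshots[[snapshot]]
  sel <- u > threshold & !model@implantMask & model@labels != 0L
  if (!is.null(region)) sel <- sel & region
  tissues <- model@properties[!model@properties$isImplant, , drop = FALSE]
  grams <- vapply(seq_len(nrow(tissues)), function(i)
    sum(sel & model@labels == tissues$label[i]) * tissues$rho[i] *
      voxelVolume(model) * 1e3, 0)
  names(grams) <- tissues$name
  c(grams, total = sum(grams))
}

#' First time a threshold is exceeded
#'
#' First crossing of the running spatial-maximum temperature increase,
#' linearly interpolated between marching steps; NA when the threshold is
#' not reached within the solved duration.
#'
#' @param state a \code{ThermalState} (uses its per-step maximum series),
#'   or a numeric series of maxima with \code{times}.
#' @param threshold threshold (K).
#' @param times step end times (s) when \code{state} is a bare series.
#' @return time (s) or NA.
#' @export
timeToThreshold <- function(state, threshold, times = NULL) {
  if (methods::is(state, "ThermalState")) {
    series <- state@maxSeries; times <- state@times
  } else series <- state
  run <- cummax(series)
  k <- which(run > threshold)
  if (!length(k)) return(NA_real_)
  k <- k[1]
  t1 <- times[k]
  dt <- if (k > 1) times[k] - times[k - 1] else times[1]
  prev <- if (k > 1) run[k - 1] else 0
  t1 - dt * (run[k] - threshold) / (run[k] - prev)
}

#' Distance from every voxel to the implant surface
#'
#' Exact Euclidean distance (m) from each voxel centre to the nearest
#' implant-surface voxel centre. The surface is the set of implant voxels
#' with at least one non-implant face neighbour.
#'
#' @param model a \code{TissueModel} with a nonempty implant.
#' @return 3D numeric array of distances (m); zero on surface voxels.
#' @export
distanceToImplant <- function(model) {
  if (!any(model@implantMask)) stop("model has no implant")
  d <- dim(model@labels)
  surf <- implantSurfaceMask(model)
  array(.edt(as.logical(surf), as.integer(d)) * model@spacing, d)
}

# Implant voxels with a non-implant face neighbour (pad counts as exposed).
implantSurfaceMask <- function(model) {
  m <- model@implantMask
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  exposed <- array(FALSE, d)
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2],
              (2:(d[3] + 1)) + s[3], drop = FALSE]
    exposed <- exposed | !nb
  }
  m & exposed
}

#' Temperature increase versus distance to the implant
#'
#' Per-voxel table of the minimum distance to the implant surface, the
#' temperature increase and the tissue name, for scatter plots of the
#' near-implant thermal halo.
#'
#' @param state a \code{ThermalState}.
#' @param model the matching \code{TissueModel}.
#' @param region optional logical mask (e.g. \code{regionOfInfluence}).
#' @param snapshot snapshot index, default the last.
#' @return data.frame with columns distance (m), deltaT (K), tissue.
#' @export
distanceProfile <- function(state, model, region = NULL,
                            snapshot = length(state@snapshots)) {
  dist <- distanceToImplant(model)
  u <- state@snapshots[[snapshot]]
  sel <- model@labels != 0L & !model@implantMask
  if (!is.null(region)) sel <- sel & region
  idx <- which(sel)
  nm <- model@properties$name[match(as.integer(model@labels[idx]),
                                    model@properties$label)]
  data.frame(distance = dist[idx], deltaT = u[idx], tissue = nm,
             stringsAsFactors = FALSE)
}

#' Assemble a safety report
#'
#' Collects the safety outputs for one exposure: maximum temperature
#' increase per snapshot (whole grid and region of influence), heated mass
#' per tissue above each threshold inside the region, and the first times
#' the thresholds are exceeded.
#'
#' @param state a \code{ThermalState}.
#' @param model the matching \code{TissueModel}.
#' @param thresholds thresholds (K), default c(1, 3).
#' @param region logical mask; default \code{regionOfInfluence(model)}.
#' @return list with elements maxDeltaT, maxDeltaTRegion, heatedMass
#'   (list per threshold), timeToThreshold (named by threshold),
#'   thresholds, snapshotTimes.
#' @export
safetyReport <- function(state, model, thresholds = c(1, 3),
                         region = regionOfInfluence(model)) {
  nSnap <- length(state@snapshots)
  mx <- vapply(seq_len(nSnap), function(j) maxDeltaT(state, snapshot = j), 0)
  mxR <- vapply(seq_len(nSnap),
                function(j) maxDeltaT(state, mask = region, snapshot = j), 0)
  masses <- lapply(thresholds, function(th)
    massAboveThreshold(state, model, th, region = region))
  names(masses) <- paste0(thresholds, "K")
  ttt <- vapply(thresholds, function(th) timeToThreshold(state, th), 0)
  names(ttt) <- paste0(thresholds, "K")
  list(maxDeltaT = mx, maxDeltaTRegion = mxR, heatedMass = masses,
       timeToThreshold = ttt, thresholds = thresholds,
       snapshotTimes = state@snapshotTimes)
}
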