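#' Synthetic RF power-deposition map
#'
#' Deterministic stand-in for a full-wave birdcage simulation: inside the
#' coil footprint the deposited power density follows the quasi-static
#' birdcage scaling P = scale * fieldScale * sigma * r^2 (r = distance from
#' the bore axis), with a raised-cosine axial roll-off over \code{rollOff}
#' metres beyond the coil ends. The map is PEC-masked (zero on implant
#' metal) and referenced to \code{referenceB1sq}. It is explicitly
#' non-physical for absolute dosimetry; its purpose is pipeline exercise
#' and relative position studies.
#'
#' @param model a \code{TissueModel} (positioned in scanner coordinates).
#' @param footprint axial extent (m) of the transmit coil, default the
#'   450 mm body coil centred at the isocenter.
#' @param rollOff axial roll-off length (m) beyond the coil ends.
#' @param referenceB1sq reference mean-square B1 (T^2).
#' @param scale deposition scale constant, W/m^3 per (S/m m^2).
#' @param fieldScale static-field factor (1 for the 1.5 T configuration;
#'   ~3.8, the squared Larmor-frequency ratio, for 3 T).
#' @return an \code{\link{RFPowerMap}}.
#' @export
syntheticRFMap <- function(model, footprint = c(-0.225, 0.225),
                           rollOff = 0.15, referenceB1sq = (3e-6)^2,
                           scale = 5e5, fieldScale = 1) {
  d <- dim(model@labels)
  x <- voxelCenters(model, 1); y <- voxelCenters(model, 2)
  z <- voxelCenters(model, 3)
  r2 <- outer(x^2, y^2, "+")
  ax <- axialRollOff(z, footprint, rollOff)
  sig <- propArray(model, "sigma")
  sig[model@implantMask] <- 0            # PEC masking and liner
  P <- sig * array(rep(r2, d[3]), d) *
    array(rep(ax, each = d[1] * d[2]), d) * scale * fieldScale
  methods::new("RFPowerMap", P = P, referenceB1sq = referenceB1sq,
               footprint = footprint,
               meta = list(rollOff = rollOff, scale = scale,
                           fieldScale = fieldScale))
}

# Raised-cosine axial window: 1 inside the footprint, smooth roll to zero
# over rollOff beyond either end.
axialRollOff <- function(z, footprint, rollOff) {
  w <- numeric(length(z))
  inside <- z >= footprint[1] & z <= footprint[2]
  w[inside] <- 1
  lo <- z < footprint[1] & z > footprint[1] - rollOff
  w[lo] <- 0.5 * (1 + cos(pi * (footprint[1] - z[lo]) / rollOff))
  hi <- z > footprint[2] & z < footprint[2] + rollOff
  w[hi] <- 0.5 * (1 + cos(pi * (z[hi] - footprint[2]) / rollOff))
  w
}

#' Apply perfect-electric-conductor masking
#'
#' Zeroes the RF power density on implant metal voxels (the field does not
#' penetrate the metal; its heating is carried entirely by the gradient
#' pathway). Idempotent.
#'
#' @param map an \code{RFPowerMap}.
#' @param model the matching \code{TissueModel}.
#' @export
pecMask <- function(map, model) {
  map@P[array(as.logical(tissueLabels(model) %in%
                         model@properties$label[model@properties$isImplant &
                                                model@properties$sigma > 0]),
              dim(map@P))] <- 0
  map
}

#' Import an externally computed RF power map
#'
#' Reads a NIfTI volume of power density (W/m^3) and conservatively remaps
#' it onto the model grid. Identical grids pass through unchanged; finer
#' grids with integer per-axis ratios are block-averaged, which preserves
#' local volume integrals (total power conserved to rounding).
#'
#' @param path NIfTI file of non-negative power density.
#' @param model target \code{TissueModel}.
#' @param referenceB1sq mean-square B1 (T^2) the map is referenced to.
#' @param footprint coil axial extent (m).
#' @return an \code{\link{RFPowerMap}} (PEC-masked).
#' @export
importRFMap <- function(path, model, referenceB1sq = (3e-6)^2,
                        footprint = c(-0.225, 0.225)) {
  vol <- RNifti::readNifti(path)
  P <- array(as.numeric(vol), dim(vol))
  if (any(P < 0)) stop("RF power map contains negative values")
  dTarget <- dim(model@labels)
  if (!identical(dim(P), dTarget)) {
    ratio <- dim(P) / dTarget
    if (any(ratio != round(ratio)) || any(ratio < 1))
      stop("grid mismatch: map is ", paste(dim(P), collapse = "x"),
           ", model is ", paste(dTarget, collapse = "x"),
           "; only identical grids or integer-factor finer grids supported")
    P <- blockAverage(P, as.integer(ratio))
  }
  pecMask(methods::new("RFPowerMap", P = P, referenceB1sq = referenceB1sq,
                       footprint = footprint, meta = list(source = path)),
          model)
}

# Volume-conserving block average by integer factors per axis.
blockAverage <- function(P, f) {
  d <- dim(P)
  out <- dim(P) %/% f
  dim(P) <- c(f[1], out[1], f[2], out[2], f[3], out[3])
  res <- apply(P, c(2, 4, 6), mean)
  array(res, out)
}

#' Scale an RF map to a sequence's RF duty
#'
#' Multiplies the power density by meanSquareB1 / referenceB1sq. The
#' mean-square B1 of a timeline already includes dead-time dilution, so
#' SAR compliance achieved through dead time propagates linearly here.
#'
#' @param map an \code{RFPowerMap}.
#' @param meanSquareB1 the sequence time-averaged mean-square B1 (T^2),
#'   e.g. from \code{\link{rfMeanSquareB1}}.
#' @return rescaled \code{RFPowerMap} referenced to \code{meanSquareB1}.
#' @export
scaleToSequence <- function(map, meanSquareB1) {
  stopifnot(map@referenceB1sq > 0)
  map@P <- map@P * (meanSquareB1 / map@referenceB1sq)
  map@referenceB1sq <- meanSquareB1
  map
}

#' Whole-body specific absorption rate (W/kg)
#'
#' Total deposited RF power divided by total model mass. The implant is
#' excluded from the numerator by PEC masking but its mass counts in the
#' denominator.
#'
#' @param map an \code{RFPowerMap}.
#' @param model a \code{TissueModel}.
#' @export
sarWb <- function(map, model) {
  map <- pecMask(map, model)
  sum(map@P) * voxelVolume(model) / modelMass(model)
}

#' Total deposited RF power (W)
#' @param map an \code{RFPowerMap}.
#' @param model the matching \code{TissueModel}.
#' @export
rfTotalPower <- function(map, model) sum(map@P) * voxelVolume(model)
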