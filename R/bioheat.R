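#' Thermoregulation model parameters
#'
#' Temperature-dependent multipliers of perfusion and metabolism: the
#' perfusion coefficient is scaled by L_B = 2^(dT/deltaB) (clamped to 1 for
#' dT <= 0, capped at \code{capDefault}, or \code{capSkin} on skin), and
#' the metabolic source is scaled by L_met = metBase^dT.
#'
#' @param deltaB doubling interval of perfusion (K), default 1.6.
#' @param capDefault perfusion multiplier cap for non-skin tissue (15).
#' @param capSkin cap for skin (32).
#' @param metBase metabolic base per kelvin (1.1).
#' @export
thermoregulationModel <- function(deltaB = 1.6, capDefault = 15,
                                  capSkin = 32, metBase = 1.1) {
  stopifnot(deltaB > 0, capDefault >= 1, capSkin >= 1, metBase > 0)
  list(deltaB = deltaB, capDefault = capDefault, capSkin = capSkin,
       metBase = metBase)
}

#' Thermoregulation multipliers at a given temperature increase
#'
#' @param deltaT temperature increase (K), vectorised.
#' @param thermo a \code{\link{thermoregulationModel}}.
#' @param isSkin logical, selects the skin cap.
#' @return list with \code{LB} (perfusion multiplier) and
#'   \code{metSourceFactor} = metBase^dT - 1 (the net metabolic source is
#'   metSourceFactor * Pmet0 in the temperature-increase formulation).
#' @export
#' @examples
#' thermoregMultipliers(1.6)$LB   # exactly 2
thermoregMultipliers <- function(deltaT, thermo = thermoregulationModel(),
                                 isSkin = FALSE) {
  stopifnot(all(is.finite(deltaT)))
  cap <- ifelse(isSkin, thermo$capSkin, thermo$capDefault)
  LB <- ifelse(deltaT > 0,
               pmin(cap, 2^(deltaT / thermo$deltaB)), 1)
  list(LB = LB, metSourceFactor = thermo$metBase^pmax(deltaT, 0) - 1)
}

# Assemble per-voxel property vectors for the compiled solver.
solverArrays <- function(model) {
  lambda <- propArray(model, "lambdaTh")
  rho <- propArray(model, "rho")
  cp <- propArray(model, "cP")
  active <- model@labels != 0L
  invRhoC <- array(0, dim(model@labels))
  invRhoC[active] <- 1 / (rho[active] * cp[active])
  skinLab <- model@properties$label[model@properties$isSkin]
  list(lambda = lambda, invRhoC = invRhoC,
       hb0 = propArray(model, "hB0"), pmet0 = propArray(model, "pMet0"),
       skin = array(model@labels %in% skinLab, dim(model@labels)),
       active = active)
}

#' Solve the bioheat equation over a marching schedule
#'
#' Advances the temperature-increase field with the Douglas-Gunn time-split
#' scheme: diffusion is implicit through three directional tridiagonal
#' solves per step; the nonlinear perfusion and metabolic terms are lagged
#' one step (Picard linearization). Air voxels are excluded; the Robin
#' condition with heat-exchange coefficient \code{hAmb} acts on tissue-air
#' faces. Faces on the grid boundary are insulated by default (the phantom
#' continues axially); set \code{robinAtBounds = TRUE} to expose them.
#'
#' @param model a \code{TissueModel}.
#' @param power a \code{\link{PowerMap}} from \code{\link{combinePower}}.
#' @param snapshotTimes times (s) at which to record the full field.
#' @param thresholds temperature-increase thresholds (K) whose first
#'   crossing times are tracked per voxel (linearly interpolated).
#' @param hAmb surface heat-exchange coefficient, W/(m^2 K), default 7.
#' @param thermo a \code{\link{thermoregulationModel}}.
#' @param robinAtBounds expose grid-boundary tissue faces to ambient.
#' @param u0 optional initial temperature-increase array.
#' @return a \code{\link{ThermalState}}.
#' @export
solveBioheat <- function(model, power, snapshotTimes = NULL,
                         thresholds = c(1, 3), hAmb = 7,
                         thermo = thermoregulationModel(),
                         robinAtBounds = FALSE, u0 = NULL) {
  stopifnot(identical(as.integer(dim(model@labels)), power@dim))
  arr <- solverArrays(model)
  dt <- power@dt
  nSteps <- power@nSteps
  duration <- nSteps * dt
  if (is.null(snapshotTimes)) snapshotTimes <- duration
  snapSteps <- sort(unique(pmin(pmax(round(snapshotTimes / dt), 1L),
                                nSteps)))
  res <- .dgSolve(dim(model@labels), arr$lambda, arr$invRhoC, arr$hb0,
                  arr$pmet0, arr$skin, arr$active, model@spacing, dt,
                  as.integer(nSteps), hAmb, robinAtBounds, power@Pbase,
                  power@metalIdx - 1L, power@M, power@gram,
                  as.integer(snapSteps), as.numeric(thresholds),
                  thermo$deltaB, thermo$capDefault, thermo$capSkin,
                  thermo$metBase,
                  if (is.null(u0)) numeric(0) else as.numeric(u0))
  d <- dim(model@labels)
  snaps <- lapply(seq_along(snapSteps),
                  function(j) array(res$snapshots[, j], d))
  methods::new("ThermalState", snapshots = snaps,
               snapshotTimes = snapSteps * dt, maxSeries = res$maxSeries,
               times = seq_len(nSteps) * dt, crossTimes = res$crossTimes,
               thresholds = as.numeric(thresholds), dim = as.integer(d))
}

#' Advance the temperature field by discrete steps
#'
#' Single-entry wrapper around the Douglas-Gunn stepper for a constant
#' power density; mainly for stepwise experiments and tests.
#'
#' @param model a \code{TissueModel}.
#' @param u current temperature-increase array (K).
#' @param dt step (s).
#' @param P power-density array (W/m^3).
#' @param nSteps number of steps to take.
#' @inheritParams solveBioheat
#' @return updated temperature-increase array.
#' @export
stepBioheat <- function(model, u, dt, P, nSteps = 1L, hAmb = 7,
                        thermo = thermoregulationModel(),
                        robinAtBounds = FALSE) {
  stopifnot(length(P) == length(model@labels),
            length(u) == length(model@labels))
  arr <- solverArrays(model)
  res <- .dgSolve(dim(model@labels), arr$lambda, arr$invRhoC, arr$hb0,
                  arr$pmet0, arr$skin, arr$active, model@spacing, dt,
                  as.integer(nSteps), hAmb, robinAtBounds, as.numeric(P),
                  integer(0), matrix(0, 0, 6), matrix(0, as.integer(nSteps), 6),
                  integer(0), numeric(0), thermo$deltaB, thermo$capDefault,
                  thermo$capSkin, thermo$metBase, as.numeric(u))
  array(res$u, dim(model@labels))
}

#' Explicit-Euler reference integration
#'
#' Independent brute-force time stepper for the same spatial discretisation
#' (7-point conduction with harmonic-mean faces and the Robin condition),
#' intended as a validation oracle at small grid sizes and fine steps.
#'
#' @inheritParams stepBioheat
#' @return final temperature-increase array after \code{nSteps} steps.
#' @export
eulerReference <- function(model, dt, P, nSteps, hAmb = 7,
                           thermo = thermoregulationModel(),
                           robinAtBounds = FALSE) {
  stopifnot(length(P) == length(model@labels))
  arr <- solverArrays(model)
  res <- .eulerSolve(dim(model@labels), arr$lambda, arr$invRhoC, arr$hb0,
                     arr$pmet0, arr$skin, arr$active, model@spacing, dt,
                     as.integer(nSteps), hAmb, robinAtBounds, as.numeric(P),
                     thermo$deltaB, thermo$capDefault, thermo$capSkin,
                     thermo$metBase)
  array(res, dim(model@labels))
}

#' Crop a model to a box of voxel indices
#'
#' Extracts a subgrid (used to confine short-exposure thermal solves to the
#' neighbourhood of the implant; the cut faces become insulated grid
#' boundaries). The origin is shifted so scanner coordinates are preserved.
#'
#' @param model a \code{TissueModel}.
#' @param lo,hi integer length-3 voxel index bounds (inclusive).
#' @return a cropped \code{TissueModel}.
#' @export
cropModel <- function(model, lo, hi) {
  d <- dim(model@labels)
  stopifnot(all(lo >= 1L), all(hi <= d), all(lo <= hi))
  rng <- lapply(1:3, function(a) lo[a]:hi[a])
  labels <- model@labels[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  mask <- model@implantMask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  methods::new("TissueModel", spacing = model@spacing, labels = labels,
               implantMask = mask, properties = model@properties,
               origin = model@origin + (lo - 1L) * model@spacing,
               meta = model@meta)
}
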