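#' @import methods
#' @importFrom Rcpp sourceCpp evalCpp
#' @useDynLib implantheat, .registration = TRUE
NULL

#' Voxelized tissue/implant model
#'
#' A \code{TissueModel} holds an axis-aligned voxel grid of tissue labels on
#' an isotropic spacing, a boolean implant mask, a per-label table of
#' electrical, thermal and perfusion properties, and the position of the grid
#' corner relative to the scanner isocenter. The z axis is the bore axis;
#' label 0 is air and is excluded from all solves.
#'
#' @slot spacing isotropic voxel edge length in metres.
#' @slot labels 3D integer array of tissue labels (0 = air).
#' @slot implantMask 3D logical array marking implant (metal + liner) voxels.
#' @slot properties data.frame of per-label properties; see
#'   \code{\link{tissueTable}} for the required columns.
#' @slot origin numeric length-3: position (m) of the corner of voxel
#'   (1,1,1) (its low-x/low-y/low-z corner) relative to isocenter.
#' @slot meta list of free-form metadata (e.g. the local z of the implant
#'   head centre used by \code{\link{placeBody}}).
#'
#' @export
setClass("TissueModel",
  representation(
    spacing = "numeric",
    labels = "array",
    implantMask = "array",
    properties = "data.frame",
    origin = "numeric",
    meta = "list"
  )
)

setValidity("TissueModel", function(object) {
  msg <- character()
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (!identical(dim(object@labels), dim(object@implantMask)))
    msg <- c(msg, "labels and implantMask dimensions differ")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  used <- setdiff(unique(as.integer(object@labels)), 0L)
  if (!all(used %in% object@properties$label))
    msg <- c(msg, "every nonzero label needs a property table entry")
  if (nrow(object@properties) > 0L) {
    p <- object@properties
    if (any(p$sigma < 0) || any(p$rho <= 0) || any(p$cP <= 0) ||
        any(p$lambdaTh <= 0) || any(p$hB0 < 0) || any(p$pMet0 < 0))
      msg <- c(msg, "property table violates sign constraints")
    imp <- p[p$isImplant, , drop = FALSE]
    if (nrow(imp) > 0L && any(imp$hB0 != 0 | imp$pMet0 != 0))
      msg <- c(msg, "implant materials must have zero perfusion/metabolism")
    impLabels <- p$label[p$isImplant]
    if (any(object@implantMask & !(object@labels %in% impLabels)))
      msg <- c(msg, "implantMask contains voxels not labelled as implant material")
  }
  if (length(msg)) msg else TRUE
})

#' Sampled pulse-sequence timeline
#'
#' Holds the RF envelope magnitude and the three gradient waveforms sampled
#' over one representative interval Delta, plus the repetition / dead-time
#' schedule that tiles the exam duration.
#'
#' The representative interval is the whole-slice acquisition frame for
#' single-shot sequences (EPI) and the repetition time TR otherwise. One
#' acquisition consists of \code{repsPerAcq} repetitions of
#' (Delta + idlePerRep) followed by \code{deadTime} seconds of idle.
#'
#' @slot kind sequence family, one of "TSE", "EPI", "GRE", "TrueFISP".
#' @slot dt sample interval (s).
#' @slot rf B1 envelope magnitude samples (T), length n.
#' @slot gx,gy,gz gradient waveforms (T/m), length n.
#' @slot delta duration of the representative interval (s), = n * dt.
#' @slot repsPerAcq repetitions of Delta per acquisition.
#' @slot idlePerRep structural idle time appended to each repetition (s).
#' @slot deadTime SAR dead time appended to each acquisition (s).
#' @slot params the \code{SequenceParams} used to build the timeline.
#'
#' @export
setClass("SequenceTimeline",
  representation(
    kind = "character",
    dt = "numeric",
    rf = "numeric",
    gx = "numeric",
    gy = "numeric",
    gz = "numeric",
    delta = "numeric",
    repsPerAcq = "numeric",
    idlePerRep = "numeric",
    deadTime = "numeric",
    params = "list"
  )
)

setValidity("SequenceTimeline", function(object) {
  msg <- character()
  n <- length(object@rf)
  if (length(object@gx) != n || length(object@gy) != n ||
      length(object@gz) != n)
    msg <- c(msg, "rf and gradient waveforms must share one length")
  if (any(object@rf < 0)) msg <- c(msg, "rf envelope must be non-negative")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@deadTime < 0 || object@idlePerRep < 0)
    msg <- c(msg, "idle/dead times must be non-negative")
  sl <- object@params$maxSlew
  if (!is.null(sl)) {
    worst <- max(vapply(list(object@gx, object@gy, object@gz),
                        function(g) if (length(g) > 1L)
                          max(abs(diff(g))) / object@dt else 0, 0))
    if (worst > sl * (1 + 1e-9))
      msg <- c(msg, sprintf("slew limit violated: %.1f > %.1f T/m/s",
                            worst, sl))
  }
  if (length(msg)) msg else TRUE
})

#' Quasi-static eddy-current solution for one harmonic
#'
#' Complex current-density phasors on the implant metal voxels for a single
#' harmonic of the gradient excitation, obtained in the resistive limit
#' (reaction field neglected): E = -j*omega*(A + grad(psi)) with psi solving
#' the discrete charge-conservation problem inside the metal.
#'
#' @slot frequency harmonic frequency (Hz).
#' @slot metalIdx linear (1-based) indices of metal voxels into the model grid.
#' @slot J complex matrix (nMetal x 3) of current-density phasors (A/m^2);
#'   the time-domain current is Re(J * exp(2i*pi*f*t)).
#' @slot power time-averaged dissipated power density per metal voxel
#'   (W/m^3), |J|^2 / (2 sigma).
#' @slot dim grid dimensions of the parent model.
#'
#' @export
setClass("EddySolution",
  representation(
    frequency = "numeric",
    metalIdx = "integer",
    J = "matrix",
    power = "numeric",
    dim = "integer"
  )
)

#' Per-voxel RF power-density map
#'
#' Volumetric RF power density referenced to a stated mean-square B1, with
#' the transmit-coil axial footprint recorded. After PEC masking, the power
#' density is zero on implant metal voxels.
#'
#' @slot P 3D array of power density (W/m^3) on the model grid.
#' @slot referenceB1sq mean-square B1 (T^2) the map is referenced to.
#' @slot footprint numeric length-2, axial extent (m) of the coil in
#'   scanner coordinates.
#' @slot meta list (e.g. roll-off width, field scale).
#'
#' @export
setClass("RFPowerMap",
  representation(
    P = "array",
    referenceB1sq = "numeric",
    footprint = "numeric",
    meta = "list"
  )
)

setValidity("RFPowerMap", function(object) {
  if (any(object@P < 0)) "RF power density must be non-negative" else TRUE
})

#' Marching-step-averaged power deposition
#'
#' Compact representation of the exposure-case power density (P1 = gradient
#' only, P2 = RF only, P3 = both) averaged over each thermal marching step.
#' The gradient contribution is stored factorised: per-voxel maps
#' \code{M} of products of the per-axis eddy field patterns, contracted at
#' solve time with the per-step Gram matrix \code{gram} of time-averaged
#' gradient slew-rate products. Use \code{\link{stepPower}} to materialise
#' the full per-voxel power for one step.
#'
#' @slot case "P1", "P2" or "P3".
#' @slot dt thermal marching step (s).
#' @slot nSteps number of marching steps covering the duration.
#' @slot Pbase 3D array, step-constant power density (RF contribution, W/m^3).
#' @slot metalIdx linear indices of implant metal voxels.
#' @slot M numeric matrix (nMetal x 6): voxel maps of
#'   (Wx.Wx, Wy.Wy, Wz.Wz, Wx.Wy, Wx.Wz, Wy.Wz)/sigma.
#' @slot gram numeric matrix (nSteps x 6): per-step time averages of
#'   (gx'^2, gy'^2, gz'^2, 2 gx'gy', 2 gx'gz', 2 gy'gz').
#' @slot dim grid dimensions.
#'
#' @export
setClass("PowerMap",
  representation(
    case = "character",
    dt = "numeric",
    nSteps = "integer",
    Pbase = "array",
    metalIdx = "integer",
    M = "matrix",
    gram = "matrix",
    dim = "integer"
  )
)

#' Thermal solution state
#'
#' Temperature-increase snapshots and threshold bookkeeping produced by
#' \code{\link{solveBioheat}}.
#'
#' @slot snapshots list of 3D arrays of temperature increase (K), one per
#'   requested snapshot time.
#' @slot snapshotTimes snapshot times (s).
#' @slot maxSeries running spatial maximum of the temperature increase at
#'   every marching step (K).
#' @slot times marching-step end times (s).
#' @slot crossTimes matrix (nVoxel x nThresholds) of first-crossing times
#'   (s, NA if never crossed), linearly interpolated between steps.
#' @slot thresholds thresholds (K) tracked during the march.
#' @slot dim grid dimensions.
#'
#' @export
setClass("ThermalState",
  representation(
    snapshots = "list",
    snapshotTimes = "numeric",
    maxSeries = "numeric",
    times = "numeric",
    crossTimes = "matrix",
    thresholds = "numeric",
    dim = "integer"
  )
)

setMethod("show", "TissueModel", function(object) {
  d <- dim(object@labels)
  cat(sprintf("TissueModel: %d x %d x %d voxels @ %.3g mm\n",
              d[1], d[2], d[3], object@spacing * 1e3))
  cat(sprintf("  tissues: %s\n",
              paste(object@properties$name, collapse = ", ")))
  cat(sprintf("  implant voxels: %d  origin (m): [%.3f, %.3f, %.3f]\n",
              sum(object@implantMask), object@origin[1], object@origin[2],
              object@origin[3]))
})

setMethod("show", "SequenceTimeline", function(object) {
  cat(sprintf("SequenceTimeline: %s, dt = %.3g us, Delta = %.4g ms\n",
              object@kind, object@dt * 1e6, object@delta * 1e3))
  cat(sprintf("  schedule: %g reps/acq, idle %.4g s/rep, dead time %.4g s\n",
              object@repsPerAcq, object@idlePerRep, object@deadTime))
  cat(sprintf("  peak B1 %.3g uT, peak |G| %.3g mT/m\n",
              max(object@rf) * 1e6,
              max(abs(c(object@gx, object@gy, object@gz))) * 1e3))
})

setMethod("show", "PowerMap", function(object) {
  cat(sprintf("PowerMap (%s): %d steps of %.3g s, %d metal voxels\n",
              object@case, object@nSteps, object@dt,
              length(object@metalIdx)))
})

setMethod("show", "ThermalState", function(object) {
  cat(sprintf("ThermalState: %d snapshots (t = %s s), final max dT = %.4g K\n",
              length(object@snapshots),
              paste(signif(object@snapshotTimes, 4), collapse = ", "),
              if (length(object@maxSeries)) max(object@maxSeries) else 0))
})
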