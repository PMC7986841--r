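# Cumulative time integrals of the six slew-rate products over one
# representative interval: columns (gx'^2, gy'^2, gz'^2, gx'gy', gx'gz',
# gy'gz'), length n+1 with a leading zero. Trapezoid-free left-sum at the
# timeline resolution (dt is ~4 us; thermal steps are ~0.1 s).
gramCumulative <- function(gdot, dt) {
  prods <- cbind(gdot[, 1]^2, gdot[, 2]^2, gdot[, 3]^2,
                 gdot[, 1] * gdot[, 2], gdot[, 1] * gdot[, 3],
                 gdot[, 2] * gdot[, 3])
  rbind(0, apply(prods, 2, cumsum)) * dt
}

# Cumulative schedule integral at arbitrary times t (vector), honoring the
# repetition structure: each acquisition is repsPerAcq x (Delta + idle)
# followed by deadTime of zero power; within a repetition the first Delta
# seconds follow the cumulative table, the idle remainder adds nothing.
scheduleCumAt <- function(cum, timeline, t) {
  n <- nrow(cum) - 1L
  dt <- timeline@dt
  delta <- n * dt
  pr <- delta + timeline@idlePerRep
  pa <- timeline@repsPerAcq * pr + timeline@deadTime
  full <- cum[n + 1L, ]

  nAcq <- floor(t / pa)
  rem <- t - nAcq * pa
  nRep <- pmin(floor(rem / pr), timeline@repsPerAcq)
  rem2 <- pmin(rem - nRep * pr, delta)
  # linear interpolation into the cumulative table
  pos <- rem2 / dt
  i0 <- pmin(floor(pos), n - 1L)
  frac <- pos - i0
  partial <- cum[i0 + 1L, , drop = FALSE] * (1 - frac) +
    cum[i0 + 2L, , drop = FALSE] * frac
  outer(nAcq * timeline@repsPerAcq + nRep, full) + partial
}

#' Build the marching-step-averaged power map for an exposure case
#'
#' Assembles the volumetric power density for the three exposure cases:
#' P1 (gradient-coil only: power deposited in the implant metal), P2 (RF
#' only: power in tissue, zero in the metal), P3 (both). Each thermal
#' marching step carries the time average of the instantaneous power over
#' that step, honoring the acquisition schedule (structural idle and SAR
#' dead times contribute zero gradient power). The RF contribution is the
#' schedule-averaged map, constant across steps.
#'
#' P3 equals P1 + P2 at the power level by construction; the temperature
#' increases do not add because thermoregulation is nonlinear.
#'
#' @param case "P1", "P2" or "P3".
#' @param model the \code{TissueModel}.
#' @param timeline the \code{SequenceTimeline} (required for P1/P3).
#' @param basis gradient eddy basis from \code{\link{gradientEddyBasis}}
#'   (required for P1/P3).
#' @param rfMap a sequence-scaled \code{\link{RFPowerMap}} (required for
#'   P2/P3).
#' @param duration exposure duration (s).
#' @param thermalDt marching step (s), default 0.1.
#' @param energyFraction,maxFreq harmonic truncation controls.
#' @return a \code{\link{PowerMap}}.
#' @export
combinePower <- function(case = c("P1", "P2", "P3"), model, timeline = NULL,
                         basis = NULL, rfMap = NULL, duration = 360,
                         thermalDt = 0.1, energyFraction = 0.999,
                         maxFreq = 1e5) {
  case <- match.arg(case)
  d <- dim(model@labels)
  nSteps <- as.integer(ceiling(duration / thermalDt))
  needGC <- case %in% c("P1", "P3")
  needRF <- case %in% c("P2", "P3")

  if (needRF) {
    if (is.null(rfMap)) stop(case, " requires an RF power map")
    stopifnot(identical(dim(rfMap@P), d))
    Pbase <- pecMask(rfMap, model)@P
  } else Pbase <- array(0, d)

  if (needGC) {
    if (is.null(timeline) || is.null(basis))
      stop(case, " requires a timeline and an eddy basis")
    gdot <- slewSignals(timeline, energyFraction, maxFreq)
    cum <- gramCumulative(gdot, timeline@dt)
    tEdges <- seq(0, by = thermalDt, length.out = nSteps + 1L)
    C <- scheduleCumAt(cum, timeline, tEdges)
    gram <- (C[-1L, , drop = FALSE] - C[-(nSteps + 1L), , drop = FALSE]) /
      thermalDt
    W <- basis$W
    M <- cbind(rowSums(W[[1]]^2), rowSums(W[[2]]^2), rowSums(W[[3]]^2),
               2 * rowSums(W[[1]] * W[[2]]), 2 * rowSums(W[[1]] * W[[3]]),
               2 * rowSums(W[[2]] * W[[3]])) / basis$sigma
    metalIdx <- as.integer(basis$metalIdx)
  } else {
    gram <- matrix(0, nSteps, 6)
    metalIdx <- metalIndices(model)
    M <- matrix(0, length(metalIdx), 6)
  }

  methods::new("PowerMap", case = case, dt = thermalDt, nSteps = nSteps,
               Pbase = Pbase, metalIdx = as.integer(metalIdx), M = M,
               gram = gram, dim = as.integer(d))
}

#' Materialise the power density of one marching step
#'
#' @param power a \code{\link{PowerMap}}.
#' @param step step index (1-based).
#' @return 3D array of power density (W/m^3).
#' @export
stepPower <- function(power, step) {
  stopifnot(step >= 1L, step <= power@nSteps)
  P <- power@Pbase
  if (length(power@metalIdx))
    P[power@metalIdx] <- P[power@metalIdx] +
      as.numeric(power@M %*% power@gram[step, ])
  P
}

#' Time-integrated deposited energy (J)
#'
#' Sum over steps of the step-averaged power times step duration and voxel
#' volume; used for energy-conservation bookkeeping against the
#' instantaneous power.
#'
#' @param power a \code{\link{PowerMap}}.
#' @param voxelVol voxel volume (m^3).
#' @export
depositedEnergy <- function(power, voxelVol) {
  gcE <- sum(power@M %*% t(power@gram)) * power@dt
  rfE <- sum(power@Pbase) * power@dt * power@nSteps
  (gcE + rfE) * voxelVol
}
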