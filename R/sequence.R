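GAMMA_BAR <- 42.577e6      # gyromagnetic ratio of 1H, Hz/T
GAMMA <- 2 * pi * GAMMA_BAR

#' Sequence parameter sets
#'
#' Construct the parameter list for one of the four supported clinical
#' sequence families, pre-filled with the study's parameter sets. Flip
#' angles are degrees, durations seconds, gradients T/m.
#'
#' The TrueFISP variants alter the RF pulse duration (v1: 1 ms to 1.5 ms at
#' fixed time-bandwidth product) or the readout bandwidth (v2: 126.3 kHz to
#' 200 kHz at fixed 1 ms pulse); all other parameters are unchanged.
#'
#' @param kind "TSE", "EPI", "GRE" or "TrueFISP".
#' @param variant for TrueFISP: 0 (baseline), 1 or 2.
#' @param deadTime SAR dead time (s) appended after each acquisition.
#' @param ... overrides of individual fields.
#' @return list of class "SequenceParams".
#' @export
#' @examples
#' sequenceParams("TrueFISP")$TR   # 6.4 ms
sequenceParams <- function(kind = c("TSE", "EPI", "GRE", "TrueFISP"),
                           variant = 0L, deadTime = 0, ...) {
  kind <- match.arg(kind)
  base <- switch(kind,
    TSE = list(flip = c(90, 180), rfDur = c(1.6e-3, 1.6e-3), tbw = c(4, 4),
               TE = 6e-3, TR = 260e-3, matrix = c(128L, 128L),
               fov = c(0.45, 0.45), sliceThk = 10e-3, readBW = 69e3,
               slicesPerTR = 2L, etl = 16L, maxSlew = 180),
    EPI = list(flip = 90, rfDur = 1.6e-3, tbw = 4, TE = 21e-3, TR = 43e-3,
               matrix = c(64L, 64L), fov = c(0.182, 0.182), sliceThk = 8e-3,
               readBW = 150e3, slicesPerTR = 1L, etl = NA_integer_,
               maxSlew = 167),
    GRE = list(flip = 20, rfDur = 10e-3, tbw = 10, TE = 20e-3, TR = 500e-3,
               matrix = c(256L, 256L), fov = c(0.14, 0.14), sliceThk = 4e-3,
               readBW = 20.83e3, slicesPerTR = 11L, etl = NA_integer_,
               maxSlew = 130),
    TrueFISP = list(flip = 45, rfDur = 1e-3, tbw = 4, TE = 3.2e-3,
                    TR = 6.4e-3, matrix = c(256L, 256L), fov = c(0.12, 0.18),
                    sliceThk = 4e-3, readBW = 126.3e3, slicesPerTR = 1L,
                    etl = NA_integer_, maxSlew = 200))
  if (kind == "TrueFISP" && variant == 1L) base$rfDur <- 1.5e-3
  if (kind == "TrueFISP" && variant == 2L) base$readBW <- 200e3
  p <- utils::modifyList(
    c(base, list(kind = kind, apodization = 0.5, deadTime = deadTime,
                 maxGrad = 0.04, dt = 4e-6)),
    list(...))
  if (any(p$TE >= p$TR)) stop("TE must be smaller than TR")
  if (p$maxSlew <= 0 || p$deadTime < 0 || p$dt <= 0)
    stop("invalid sequence parameters")
  class(p) <- "SequenceParams"
  p
}

# Apodized-sinc RF envelope (T), amplitude set by pulse-area proportionality
# to the flip angle. Returns the magnitude samples.
sincPulse <- function(flipDeg, dur, tbw, apod, dt) {
  n <- max(2L, round(dur / dt))
  t <- (seq_len(n) - 0.5) * dt - dur / 2
  x <- tbw * t / dur
  env <- ((1 - apod) + apod * cos(2 * pi * t / dur)) *
    ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  amp <- (flipDeg * pi / 180) / (GAMMA * sum(env) * dt)
  abs(amp * env)
}

# Minimal-duration trapezoid (or triangle) with prescribed zeroth moment
# `area` (T s / m), honoring slew and amplitude limits. Sample k sits at the
# end of the k-th dt interval so the discrete sum equals the area exactly.
trapezoidLobe <- function(area, slew, gmax, dt) {
  if (abs(area) < .Machine$double.eps) return(numeric(0))
  s <- sign(area); a <- abs(area)
  gPeak <- min(gmax, sqrt(a * slew))
  nr <- ceiling(gPeak / (slew * dt))
  flat <- max(0, a / gPeak - nr * dt)   # continuous estimate
  nf <- ceiling(flat / dt)
  # discrete area of unit-peak shape: ramps contribute nr*dt (two half ramps)
  shape <- c(seq_len(nr) / nr, rep(1, nf), rev(seq_len(nr) - 1) / nr)
  g <- a / (sum(shape) * dt)
  while (g / (nr * dt) > slew * (1 + 1e-12) || g > gmax * (1 + 1e-12)) {
    if (g > gmax * (1 + 1e-12)) nf <- nf + 1L else nr <- nr + 1L
    shape <- c(seq_len(nr) / nr, rep(1, nf), rev(seq_len(nr) - 1) / nr)
    g <- a / (sum(shape) * dt)
  }
  s * g * shape
}

# Flat-top readout lobe: prescribed plateau amplitude and flat duration.
readoutLobe <- function(amp, flatDur, slew, dt) {
  if (amp == 0) return(numeric(0))
  nr <- ceiling(abs(amp) / (slew * dt))
  nf <- max(1L, round(flatDur / dt))
  amp * c(seq_len(nr) / nr, rep(1, nf), rev(seq_len(nr) - 1) / nr)
}

# Mutable-cursor waveform assembler over n samples.
newAssembler <- function(n) {
  env <- new.env(parent = emptyenv())
  env$rf <- numeric(n); env$gx <- numeric(n); env$gy <- numeric(n)
  env$gz <- numeric(n); env$cursor <- 0L; env$n <- n
  env
}

place <- function(asm, channel, samples, at = asm$cursor, advance = TRUE,
                  label = "lobe") {
  m <- length(samples)
  if (m == 0L) return(invisible(asm))
  if (at + m > asm$n)
    stop("infeasibility error: ", label,
         " does not fit in the representative interval (needs ",
         at + m, " of ", asm$n, " samples)")
  idx <- (at + 1L):(at + m)
  asm[[channel]][idx] <- asm[[channel]][idx] + samples
  if (advance) asm$cursor <- at + m
  invisible(asm)
}

# Place several lobes on different channels starting together; the cursor
# advances by the longest one.
placeConcurrent <- function(asm, lobes, label = "concurrent lobes") {
  start <- asm$cursor
  for (ch in names(lobes))
    place(asm, ch, lobes[[ch]], at = start, advance = FALSE, label = label)
  asm$cursor <- start + max(vapply(lobes, length, 1L))
  invisible(asm)
}

# Slice-selection block: gradient plateau covering the RF pulse, ramps at
# the slew limit; returns the refocusing area (area from RF centre to end).
sliceBlock <- function(asm, p, flip, rfDur, tbw, slew, dt, rephase = TRUE,
                       balance = FALSE) {
  bw <- tbw / rfDur
  gss <- bw / (GAMMA_BAR * p$sliceThk)
  nr <- ceiling(gss / (slew * dt))
  nf <- max(2L, round(rfDur / dt))
  lobe <- gss * c(seq_len(nr) / nr, rep(1, nf), rev(seq_len(nr) - 1) / nr)
  rfs <- sincPulse(flip, rfDur, tbw, p$apodization, dt)
  if (balance)  # prephase half the slice area for balanced sequences
    place(asm, "gz", trapezoidLobe(-sum(lobe) * dt / 2, slew, p$maxGrad, dt),
          label = "slice prephaser")
  start <- asm$cursor
  place(asm, "gz", lobe, label = "slice gradient")
  place(asm, "rf", rfs, at = start + nr + (nf - length(rfs)) %/% 2,
        advance = FALSE, label = "rf pulse")
  refocusArea <- -(sum(lobe) * dt / 2)
  if (rephase)
    place(asm, "gz", trapezoidLobe(refocusArea, slew, p$maxGrad, dt),
          label = "slice rephaser")
  invisible(refocusArea)
}

#' Synthesize the sequence timeline
#'
#' Builds the sampled RF envelope and the three gradient waveforms over one
#' representative interval Delta, following the standard gradient-moment
#' relations: readout amplitude from readout bandwidth and FOV, phase-encode
#' areas from the k-space step 1/FOV, slice-select amplitude from the RF
#' bandwidth and slice thickness. Trapezoids ramp at the slew limit; sinc
#' pulses carry the stated duration, time-bandwidth product and apodization,
#' with amplitude proportional to flip angle via the pulse area.
#'
#' Delta is the TR for TSE/GRE/TrueFISP and the whole-slice acquisition
#' frame for EPI. TSE emits one 90 degree excitation followed by
#' echo-train-length 180 degree pulses per slice block; its acquisition unit
#' is matrix/ETL = 8 repetitions of TR, after which the SAR dead time is
#' inserted.
#'
#' @param params a \code{\link{sequenceParams}} list.
#' @return a \code{\link{SequenceTimeline}}.
#' @export
buildSequence <- function(params) {
  p <- params
  dt <- p$dt
  fovRead <- p$fov[1]; fovPhase <- p$fov[2]
  gRead <- p$readBW / (GAMMA_BAR * fovRead)
  if (gRead > p$maxGrad)
    stop("infeasibility error: readout plateau exceeds the gradient limit")
  readFlat <- p$matrix[1] / p$readBW
  kStep <- 1 / (GAMMA_BAR * fovPhase)   # phase-encode area per line

  build <- switch(p$kind, TSE = buildTSE, EPI = buildEPI, GRE = buildGRE,
                  TrueFISP = buildFISP)
  tl <- build(p, dt, gRead, readFlat, kStep)
  methods::new("SequenceTimeline", kind = p$kind, dt = dt, rf = tl$asm$rf,
               gx = tl$asm$gx, gy = tl$asm$gy, gz = tl$asm$gz,
               delta = tl$asm$n * dt, repsPerAcq = tl$repsPerAcq,
               idlePerRep = tl$idlePerRep, deadTime = p$deadTime,
               params = unclass(p))
}

buildTSE <- function(p, dt, gRead, readFlat, kStep) {
  n <- round(p$TR / dt)
  asm <- newAssembler(n)
  slew <- p$maxSlew
  halfRead <- gRead * (readFlat + ceiling(gRead / (slew * dt)) * dt) / 2
  lines <- seq(-p$matrix[2] / 2, by = p$matrix[2] / p$etl,
               length.out = p$etl)        # representative shot
  for (s in seq_len(p$slicesPerTR)) {
    sliceBlock(asm, p, p$flip[1], p$rfDur[1], p$tbw[1], slew, dt)
    for (e in seq_len(p$etl)) {
      sliceBlock(asm, p, p$flip[2], p$rfDur[2], p$tbw[2], slew, dt,
                 rephase = FALSE)
      place(asm, "gy", trapezoidLobe(lines[e] * kStep, slew, p$maxGrad, dt),
            label = "phase encode")
      place(asm, "gx", trapezoidLobe(-halfRead, slew, p$maxGrad, dt),
            label = "read prephaser")
      place(asm, "gx", readoutLobe(gRead, readFlat, slew, dt),
            label = "readout")
      place(asm, "gx", trapezoidLobe(-halfRead, slew, p$maxGrad, dt),
            label = "read rewinder")
      place(asm, "gy", trapezoidLobe(-lines[e] * kStep, slew, p$maxGrad, dt),
            label = "phase rewinder")
    }
  }
  list(asm = asm, repsPerAcq = p$matrix[2] / p$etl, idlePerRep = 0)
}

buildEPI <- function(p, dt, gRead, readFlat, kStep) {
  slew <- p$maxSlew
  nr <- ceiling(gRead / (slew * dt))
  # frame length: excitation + prephasers + echo train (sized generously)
  est <- round((p$rfDur * 2.5 + 2e-3 +
                p$matrix[2] * (readFlat + 2 * nr * dt)) / dt) + 200L
  asm <- newAssembler(est)
  halfRead <- gRead * (readFlat + nr * dt) / 2
  sliceBlock(asm, p, p$flip, p$rfDur, p$tbw, slew, dt)
  place(asm, "gy", trapezoidLobe(-p$matrix[2] / 2 * kStep, slew, p$maxGrad,
                                 dt), label = "phase prephaser")
  place(asm, "gx", trapezoidLobe(-halfRead, slew, p$maxGrad, dt),
        label = "read prephaser")
  blip <- trapezoidLobe(kStep, slew, p$maxGrad, dt)
  for (e in seq_len(p$matrix[2])) {
    start <- asm$cursor
    place(asm, "gx", readoutLobe(gRead * (-1)^(e - 1), readFlat, slew, dt),
          label = "epi readout")
    if (e < p$matrix[2])  # blip during the ramp transition
      place(asm, "gy", blip, at = asm$cursor - length(blip) %/% 2,
            advance = FALSE, label = "phase blip")
  }
  used <- asm$cursor + 2L
  for (ch in c("rf", "gx", "gy", "gz")) asm[[ch]] <- asm[[ch]][seq_len(used)]
  asm$n <- used
  frame <- used * dt
  list(asm = asm, repsPerAcq = 1, idlePerRep = max(0, p$TR - frame))
}

buildGRE <- function(p, dt, gRead, readFlat, kStep) {
  n <- round(p$TR / dt)
  asm <- newAssembler(n)
  slew <- p$maxSlew
  halfRead <- gRead * (readFlat + ceiling(gRead / (slew * dt)) * dt) / 2
  peArea <- p$matrix[2] / 2 * kStep      # outermost line, representative
  for (s in seq_len(p$slicesPerTR)) {
    sliceBlock(asm, p, p$flip, p$rfDur, p$tbw, slew, dt)
    place(asm, "gy", trapezoidLobe(peArea, slew, p$maxGrad, dt),
          label = "phase encode")
    place(asm, "gx", trapezoidLobe(-halfRead, slew, p$maxGrad, dt),
          label = "read prephaser")
    place(asm, "gx", readoutLobe(gRead, readFlat, slew, dt),
          label = "readout")
    place(asm, "gy", trapezoidLobe(-peArea, slew, p$maxGrad, dt),
          label = "phase rewinder")
    place(asm, "gz", trapezoidLobe(2 * peArea, slew, p$maxGrad, dt),
          label = "spoiler")
  }
  list(asm = asm, repsPerAcq = 1, idlePerRep = 0)
}

buildFISP <- function(p, dt, gRead, readFlat, kStep) {
  n <- round(p$TR / dt)
  asm <- newAssembler(n)
  slew <- p$maxSlew
  halfRead <- gRead * (readFlat + ceiling(gRead / (slew * dt)) * dt) / 2
  peArea <- p$matrix[2] / 2 * kStep
  sliceBlock(asm, p, p$flip, p$rfDur, p$tbw, slew, dt, rephase = FALSE,
             balance = TRUE)
  # fully balanced TR: rephase/prepare lobes run concurrently per channel
  sliceArea <- sum(asm$gz) * dt  # prephaser already subtracted half
  placeConcurrent(asm, list(
    gz = trapezoidLobe(-sliceArea, slew, p$maxGrad, dt),
    gx = trapezoidLobe(-halfRead, slew, p$maxGrad, dt),
    gy = trapezoidLobe(peArea, slew, p$maxGrad, dt)), "balance lobes")
  place(asm, "gx", readoutLobe(gRead, readFlat, slew, dt), label = "readout")
  placeConcurrent(asm, list(
    gx = trapezoidLobe(-halfRead, slew, p$maxGrad, dt),
    gy = trapezoidLobe(-peArea, slew, p$maxGrad, dt)), "rewind lobes")
  list(asm = asm, repsPerAcq = 1, idlePerRep = 0)
}

#' Active time per acquisition (s)
#'
#' The repeated active block of the schedule: repsPerAcq * (Delta + idle).
#' For the TSE parameter set this is 8 * TR = 2.08 s.
#' @param timeline a \code{SequenceTimeline}.
#' @export
acquisitionDuration <- function(timeline)
  timeline@repsPerAcq * (timeline@delta + timeline@idlePerRep)

#' Time-averaged mean-square B1 over one schedule period
#'
#' Averages |B1|^2 over one acquisition period including structural idle and
#' the SAR dead time; quadratic in pulse amplitude, linear in duty cycle.
#' @param timeline a \code{SequenceTimeline}.
#' @return mean-square B1 (T^2).
#' @export
rfMeanSquareB1 <- function(timeline) {
  if (length(timeline@rf) == 0L) stop("empty timeline")
  active <- sum(timeline@rf^2) * timeline@dt * timeline@repsPerAcq
  active / (acquisitionDuration(timeline) + timeline@deadTime)
}

#' Dead time needed for whole-body SAR compliance
#'
#' Idle time to insert after each acquisition so that the time-averaged
#' whole-body SAR over (active + dead) equals the limit:
#' max(0, tActive * (sar/limit - 1)). Applying the rule to an already
#' compliant sequence returns 0.
#'
#' @param sarUnscaled whole-body SAR of the uninterrupted sequence (W/kg).
#' @param tActive active time per acquisition (s).
#' @param sarLimit limit (W/kg), default 2.
#' @return dead time (s).
#' @export
#' @examples
#' deadTimeForSAR(7.43, 2.08)   # 3 T TSE worst case, ~5.65 s
#' deadTimeForSAR(2.29, 2.08)   # 1.5 T TSE, ~0.30 s
deadTimeForSAR <- function(sarUnscaled, tActive, sarLimit = 2) {
  stopifnot(sarUnscaled > 0, tActive > 0, sarLimit > 0)
  max(0, tActive * (sarUnscaled / sarLimit - 1))
}

#' Number of acquisitions within a total exam time
#'
#' Round-to-nearest of totalTime / (tActive + deadTime); the rounding rule
#' reproduces both the dense (151 in 360 s) and the sparse (47 in 360 s)
#' dead-time schedules of the compliant TSE protocol.
#' @param totalTime exam duration (s).
#' @param tActive active time per acquisition (s).
#' @param deadTime dead time per acquisition (s).
#' @export
countAcquisitions <- function(totalTime, tActive, deadTime = 0) {
  stopifnot(totalTime >= 0, tActive > 0, deadTime >= 0)
  round(totalTime / (tActive + deadTime))
}

#' Export the sampled timeline as CSV
#'
#' Writes one row per sample with columns t, rf, gx, gy, gz.
#' @param timeline a \code{SequenceTimeline}.
#' @param path output file.
#' @export
writeTimelineCSV <- function(timeline, path) {
  n <- length(timeline@rf)
  utils::write.csv(data.frame(t = (seq_len(n) - 1) * timeline@dt,
                              rf = timeline@rf, gx = timeline@gx,
                              gy = timeline@gy, gz = timeline@gz),
                   path, row.names = FALSE)
}
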