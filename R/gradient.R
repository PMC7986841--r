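MU0 <- 4e-7 * pi

#' Gradient-coil model
#'
#' Either an idealized uniform-gradient model (linear field maps with the
#' stated per-axis sensitivities) or a filamentary conductor model whose
#' field is computed by the Biot-Savart law.
#'
#' @param mode "uniform" or "filamentary".
#' @param sensitivities gradient per unit current for the x, y, z coils,
#'   in microtesla/(m A); defaults 56.1, 56.1, 57.8.
#' @param filaments for filamentary mode: a list with one element per axis,
#'   each a list(start, end, current) of segment endpoint matrices (n x 3, m)
#'   and per-segment currents (A) for unit gradient excitation.
#' @param linearRegion half-extent (m) of the region where the uniform
#'   model is trusted; points beyond are flagged.
#' @export
coilModel <- function(mode = c("uniform", "filamentary"),
                      sensitivities = c(56.1, 56.1, 57.8),
                      filaments = NULL, linearRegion = 0.45) {
  mode <- match.arg(mode)
  if (any(sensitivities <= 0)) stop("sensitivities must be positive")
  if (mode == "filamentary" && (is.null(filaments) || !length(filaments)))
    stop("filamentary mode requires a nonempty filament list")
  structure(list(mode = mode, sensitivities = sensitivities,
                 filaments = filaments, linearRegion = linearRegion),
            class = "CoilModel")
}

#' Magnetic flux density of straight filament segments
#'
#' Biot-Savart sum over line segments, each treated with the exact
#' finite-segment formula.
#'
#' @param start,end matrices (n x 3) of segment endpoints (m).
#' @param current per-segment currents (A), recycled.
#' @param points matrix (m x 3) of field points (m).
#' @return matrix (m x 3) of B (T).
#' @export
biotSavart <- function(start, end, current, points) {
  current <- rep_len(current, nrow(start))
  B <- matrix(0, nrow(points), 3)
  for (s in seq_len(nrow(start))) {
    a <- sweep(points, 2, start[s, ])     # from segment start to point
    b <- sweep(points, 2, end[s, ])
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    cr2 <- rowSums(cr^2)
    # exact finite segment: B = mu0 I/(4 pi) * cross(a,b) *
    #   (na + nb) / (na * nb * (na * nb + dot(a, b)))
    denom <- na * nb * (na * nb + rowSums(a * b))
    f <- ifelse(cr2 < 1e-30 | denom < 1e-30, 0, (na + nb) / denom)
    B <- B + MU0 * current[s] / (4 * pi) * cr * f
  }
  B
}

#' Gradient-coil source field
#'
#' For the uniform-gradient model, returns the idealized linear field map:
#' a pure z-component equal to gradient times the coordinate along the coil
#' axis (x, y or z), the standard concomitant-free idealization. For the
#' filamentary model, the Biot-Savart sum over the axis's winding scaled to
#' the requested gradient via the coil sensitivity.
#'
#' @param coil a \code{\link{coilModel}}.
#' @param points matrix (n x 3) of positions (m).
#' @param axis "x", "y" or "z".
#' @param gradient gradient strength (T/m).
#' @return matrix (n x 3) of B (T), with attribute "outsideLinearRegion"
#'   flagging points beyond the trusted region in uniform mode.
#' @export
sourceField <- function(coil, points, axis = c("x", "y", "z"),
                        gradient = 1) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  if (coil$mode == "uniform") {
    B <- matrix(0, nrow(points), 3)
    B[, 3] <- gradient * points[, ai]
    out <- abs(points[, ai]) > coil$linearRegion
    if (any(out)) warning("points outside the gradient linear region")
    attr(B, "outsideLinearRegion") <- out
    B
  } else {
    f <- coil$filaments[[ai]]
    current <- f$current * gradient / (coil$sensitivities[ai] * 1e-6)
    biotSavart(f$start, f$end, current, points)
  }
}

# Unit-gradient vector potentials in the symmetric gauge. These generate
# the Maxwell-consistent linear fields (including concomitant components):
#   x coil: B = G (z, 0, x);  y coil: B = G (0, z, y);
#   z coil: B = G (-x/2, -y/2, z).
unitVectorPotential <- function(axis) {
  switch(axis,
    x = function(p) cbind(0, (p[, 1]^2 - p[, 3]^2) / 2, 0),
    y = function(p) cbind((p[, 3]^2 - p[, 2]^2) / 2, 0, 0),
    z = function(p) cbind(-p[, 2] * p[, 3] / 2, p[, 1] * p[, 3] / 2, 0),
    stop("axis must be x, y or z"))
}

# --- quasi-static eddy-current solver ---------------------------------------

# Union-find connected components over an edge list on 1..n.
connectedComponents <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    a <- find(from[e]); b <- find(to[e])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 1L)
}

# Internal: solve the discrete charge-conservation problem inside the metal.
# Given a vector-potential function Afun (points -> n x 3), finds psi with
# div(sigma (A + grad psi)) = 0, zero normal current on the metal surface.
# Returns centre-evaluated field W = sigma (A + grad psi) (per voxel, 3
# components), which multiplied by -dG/dt (or -j omega for a phasor) gives
# the current density.
eddyFieldPattern <- function(model, Afun) {
  dx <- model@spacing
  d <- dim(model@labels)
  idx <- metalIndices(model)
  if (!length(idx)) stop("metal mask is empty")
  n <- length(idx)
  map <- integer(prod(d)); map[idx] <- seq_len(n)
  sig <- propArray(model, "sigma")[idx]

  ijk <- arrayInd(idx, d)
  centers <- (ijk - 0.5) * dx + matrix(model@origin, n, 3, byrow = TRUE)

  shifts <- c(1L, d[1], d[1] * d[2])
  fromAll <- integer(0); toAll <- integer(0); gAll <- numeric(0)
  aAll <- numeric(0); axAll <- integer(0)
  for (ax in 1:3) {
    ok <- ijk[, ax] < d[ax]
    nb <- map[idx[ok] + shifts[ax]]
    ok2 <- which(ok)[nb > 0]
    nb <- nb[nb > 0]
    if (!length(nb)) next
    i <- map[idx[ok2]]
    g <- 2 * sig[i] * sig[nb] / (sig[i] + sig[nb])
    faceC <- centers[i, , drop = FALSE]
    faceC[, ax] <- faceC[, ax] + dx / 2
    aFace <- Afun(faceC)[, ax]
    fromAll <- c(fromAll, i); toAll <- c(toAll, nb)
    gAll <- c(gAll, g); aAll <- c(aAll, aFace); axAll <- c(axAll, rep(ax, length(i)))
  }

  # Laplacian with face conductances g/dx; RHS collects -sum(+/- g * A_face)
  L <- Matrix::sparseMatrix(
    i = c(fromAll, toAll, fromAll, toAll),
    j = c(toAll, fromAll, fromAll, toAll),
    x = c(-gAll, -gAll, gAll, gAll) / dx,
    dims = c(n, n))
  b <- numeric(n)
  bb <- gAll * aAll                       # face source flux
  agg <- rowsum(c(bb, -bb), c(fromAll, toAll))
  b[as.integer(rownames(agg))] <- agg[, 1]

  comp <- connectedComponents(n, fromAll, toAll)
  pins <- match(unique(comp), comp)
  pen <- Matrix::sparseMatrix(i = pins, j = pins,
                              x = rep(max(gAll) / dx * 1e8, length(pins)),
                              dims = c(n, n))
  psi <- as.numeric(Matrix::solve(Matrix::forceSymmetric(L + pen, uplo = "U"),
                                  b))

  # centre gradients of psi and A at centres
  gradPsi <- matrix(0, n, 3)
  for (ax in 1:3) {
    sel <- axAll == ax
    f <- fromAll[sel]; t <- toAll[sel]
    dpsi <- (psi[t] - psi[f]) / dx
    num <- numeric(n); den <- numeric(n)
    num[f] <- num[f] + dpsi; den[f] <- den[f] + 1
    num[t] <- num[t] + dpsi; den[t] <- den[t] + 1
    gradPsi[, ax] <- ifelse(den > 0, num / pmax(den, 1), 0)
  }
  W <- sig * (Afun(centers) + gradPsi)
  list(W = W, psi = psi, metalIdx = idx, sigma = sig, comp = comp,
       edges = list(from = fromAll, to = toAll, g = gAll, a = aAll,
                    axis = axAll))
}

#' Solve the eddy-current problem for one harmonic
#'
#' Quasi-static (resistive-limit) solution of the induced currents in the
#' implant for a time-harmonic source described by its vector potential:
#' E = -j omega (A + grad psi), with psi solving the discrete conservation
#' problem div(sigma E) = 0 inside the metal and zero normal current through
#' the metal surface. The reaction (secondary) magnetic field is neglected;
#' a warning is issued when the skin depth at the requested frequency drops
#' below the smallest implant part dimension.
#'
#' @param model a \code{TissueModel} with a nonempty metal mask.
#' @param frequency harmonic frequency (Hz), >= 0.
#' @param Afun vector-potential field of the source at unit excitation:
#'   a function mapping an (n x 3) matrix of positions (m) to an (n x 3)
#'   matrix of A (T m). For a uniform axial field B, use
#'   \code{function(p) cbind(-p[,2], p[,1], 0) * B / 2}; for unit-gradient
#'   coil fields see \code{\link{unitVectorPotential}}.
#' @param amplitude complex amplitude multiplying the unit excitation.
#' @return an \code{\link{EddySolution}}.
#' @export
solveEddyHarmonic <- function(model, frequency, Afun, amplitude = 1) {
  stopifnot(frequency >= 0)
  pat <- eddyFieldPattern(model, Afun)
  omega <- 2 * pi * frequency
  skinDepthWarning(model, frequency)
  J <- (-1i) * omega * amplitude * pat$W
  power <- rowSums(Mod(J)^2) / (2 * pat$sigma)
  methods::new("EddySolution", frequency = frequency,
               metalIdx = as.integer(pat$metalIdx), J = J, power = power,
               dim = dim(model@labels))
}

skinDepthWarning <- function(model, frequency) {
  if (frequency <= 0) return(invisible(NULL))
  idx <- metalIndices(model)
  sig <- max(propArray(model, "sigma")[idx])
  delta <- sqrt(2 / (MU0 * sig * 2 * pi * frequency))
  ijk <- arrayInd(idx, dim(model@labels))
  ext <- (apply(ijk, 2, max) - apply(ijk, 2, min) + 1) * model@spacing
  if (delta < min(ext))
    warning(sprintf(paste("skin depth %.1f mm below smallest implant",
                          "extent %.1f mm at %.3g Hz;",
                          "resistive-limit solution degrades"),
                    delta * 1e3, min(ext) * 1e3, frequency))
  invisible(delta)
}

#' Total time-averaged eddy power (W)
#' @param solution an \code{EddySolution}.
#' @param spacing voxel edge (m).
#' @export
eddyTotalPower <- function(solution, spacing)
  sum(solution@power) * spacing^3

# --- subsignal splitting and harmonic decomposition -------------------------

#' Split a gradient channel into subsignals
#'
#' Partitions the sampled waveform over the representative interval into
#' contiguous subsignals, each classified periodic or aperiodic.
#' Quiescent runs (below tolerance, at least \code{minGap} samples) become
#' their own all-zero aperiodic subsignals; active runs are classified
#' periodic when a shift by some period reproduces the run to within
#' \code{periodTol} relative RMS. Explicit breakpoints override detection.
#' The concatenation of the subsignal samples always reproduces the input
#' exactly.
#'
#' @param g numeric waveform samples.
#' @param dt sample interval (s).
#' @param breaks optional increasing integer vector of segment start
#'   indices (must begin with 1).
#' @param minGap minimal quiescent run length (samples) splitting segments.
#' @param periodTol relative RMS tolerance of the periodicity test.
#' @return list of subsignals: each list(samples, start, dt, class, period).
#' @export
splitIntoSubsignals <- function(g, dt, breaks = NULL, minGap = 256L,
                                periodTol = 0.005) {
  n <- length(g)
  if (n < 1L) stop("empty signal")
  if (is.null(breaks)) {
    tol <- 1e-9 * max(abs(g), 1e-30)
    quiet <- abs(g) <= tol
    r <- rle(quiet)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    keep <- r$values & r$lengths >= minGap
    cuts <- sort(unique(c(1L, starts[keep], ends[keep] + 1L)))
    breaks <- cuts[cuts <= n]
  } else {
    if (breaks[1] != 1L || is.unsorted(breaks, strictly = TRUE) ||
        any(breaks > n))
      stop("breaks must be strictly increasing, start at 1 and stay in range")
  }
  bounds <- c(breaks, n + 1L)
  out <- list()
  for (i in seq_along(breaks)) {
    s <- g[bounds[i]:(bounds[i + 1] - 1L)]
    for (piece in refineSegment(s, periodTol)) {
      piece$start <- bounds[i] + piece$start - 1L
      piece$dt <- dt
      out[[length(out) + 1L]] <- piece
    }
  }
  out
}

# Change-point refinement of one contiguous active run: detect a dominant
# lobe period from autocorrelation local maxima, then find the longest
# p-periodic suffix; anything before it becomes an aperiodic subsignal
# (e.g. EPI prephaser lobes ahead of the readout train).
refineSegment <- function(s, tol = 0.005) {
  L <- length(s)
  ms <- mean(s^2)
  whole <- function(cls, per) list(list(samples = s, start = 1L,
                                        class = cls, period = per))
  if (ms == 0 || L < 16L) return(whole("aperiodic", NA_integer_))
  # candidate lobe periods from the whole run and from suffix windows (an
  # energetic aperiodic prefix would otherwise swamp the autocorrelation)
  cand <- sort(unique(c(periodCandidates(s),
                        periodCandidates(s[(L %/% 2 + 1L):L]),
                        periodCandidates(s[(3L * L %/% 4 + 1L):L]))))
  for (p in cand) {
    d2 <- (s[1:(L - p)] - s[(p + 1):L])^2
    if (mean(d2) / ms < tol) {            # entire run periodic
      if (L >= 2L * p) return(whole("periodic", p))
      next
    }
    # longest suffix with running mismatch below tolerance
    revCum <- rev(cumsum(rev(d2)))
    nTail <- (L - p) : 1
    okFrom <- which(revCum / (nTail * ms) < tol)
    if (!length(okFrom)) next
    m <- okFrom[1]                        # suffix s[m:L] is p-periodic
    if (L - m + 1L < 2L * p || m < 8L) next
    return(list(
      list(samples = s[1:(m - 1L)], start = 1L, class = "aperiodic",
           period = NA_integer_),
      list(samples = s[m:L], start = m, class = "periodic", period = p)))
  }
  whole("aperiodic", NA_integer_)
}

# Candidate lobe periods: local maxima of the normalized FFT
# autocorrelation above 0.5, smallest first; lags below 4 samples excluded.
periodCandidates <- function(s, maxCandidates = 8L) {
  L <- length(s)
  n2 <- 2^ceiling(log2(2 * L))
  F <- stats::fft(c(s, numeric(n2 - L)))
  r <- Re(stats::fft(Mod(F)^2, inverse = TRUE))[seq_len(L %/% 2 + 1)] / n2
  rn <- r / pmax(L - (0:(L %/% 2)), 1) / mean(s^2)
  k <- 2:(length(rn) - 1)
  peaks <- k[rn[k] >= rn[k - 1] & rn[k] >= rn[k + 1] & rn[k] > 0.5]
  lags <- peaks - 1L
  utils::head(lags[lags >= 4L], maxCandidates)
}

#' Truncated Fourier decomposition of a subsignal
#'
#' FFT of the subsignal; conjugate-pair coefficient groups are ordered by
#' descending energy and retained until the requested fraction of the
#' mean-square signal energy is captured (Parseval bookkeeping is exposed).
#' Coefficients above \code{maxFreq} are excluded before selection.
#'
#' @param sub a subsignal from \code{\link{splitIntoSubsignals}}, or a
#'   numeric vector (then \code{dt} must be given).
#' @param energyFraction target captured energy fraction, default 0.999.
#' @param maxFreq cap (Hz) on retained harmonic frequency, default 100 kHz.
#' @param dt sample interval when \code{sub} is a bare vector.
#' @return list: \code{freq} signed frequencies (Hz) of retained
#'   coefficients, \code{coef} complex two-sided coefficients (signal =
#'   sum coef_k exp(2i pi f_k t)), \code{n}, \code{dt}, \code{start},
#'   \code{achieved} captured energy fraction, \code{meanSquare}.
#' @export
harmonicDecompose <- function(sub, energyFraction = 0.999, maxFreq = 1e5,
                              dt = NULL) {
  if (is.numeric(sub)) sub <- list(samples = sub, start = 1L, dt = dt)
  s <- sub$samples
  N <- length(s)
  if (N < 2L) stop("subsignal must have at least 2 samples")
  X <- stats::fft(s) / N
  k <- 0:(N - 1)
  f <- ifelse(k <= N / 2, k, k - N) / (N * sub$dt)
  E <- Mod(X)^2                       # Parseval: sum(E) == mean(s^2)
  group <- pmin(k, (N - k) %% N)      # conjugate pairs share a group
  gE <- tapply(E, group, sum)
  gIds <- as.integer(names(gE))
  gF <- gIds / (N * sub$dt)
  ord <- order(gE, decreasing = TRUE)
  ord <- ord[gF[ord] <= maxFreq]
  total <- sum(E)
  keepG <- integer(0); acc <- 0
  for (o in ord) {
    if (acc >= energyFraction * total && acc > 0) break
    keepG <- c(keepG, gIds[o]); acc <- acc + gE[o]
  }
  keep <- which(group %in% keepG & E > 0)
  if (!length(keep) && total == 0) keep <- 1L   # all-zero signal: DC only
  list(freq = f[keep], coef = X[keep], index = k[keep], n = N, dt = sub$dt,
       start = sub$start,
       achieved = if (total > 0) acc / total else 1, meanSquare = total)
}

#' Reconstruct a subsignal (or its time derivative) from retained harmonics
#'
#' Inverse transform over the subsignal's own sample grid. With
#' \code{derivative = TRUE} returns the time derivative (the Nyquist bin,
#' if retained, is dropped to keep the derivative real).
#'
#' @param hs a decomposition from \code{\link{harmonicDecompose}}.
#' @param derivative return d/dt of the truncated signal.
#' @return numeric vector of length \code{hs$n}.
#' @export
reconstructSubsignal <- function(hs, derivative = FALSE) {
  Z <- complex(length.out = hs$n)
  co <- hs$coef
  if (derivative) {
    co <- co * 2i * pi * hs$freq
    co[abs(abs(hs$freq) - 1 / (2 * hs$dt)) < 1e-9] <- 0
  }
  Z[hs$index + 1L] <- co
  Re(stats::fft(Z, inverse = TRUE))
}

# Truncated slew-rate (dG/dt) signals for the three gradient channels over
# one representative interval; the per-channel subsignal structure follows
# splitIntoSubsignals.
slewSignals <- function(timeline, energyFraction = 0.999, maxFreq = 1e5) {
  out <- matrix(0, length(timeline@rf), 3)
  achieved <- numeric(3)
  chans <- list(timeline@gx, timeline@gy, timeline@gz)
  for (a in 1:3) {
    subs <- splitIntoSubsignals(chans[[a]], timeline@dt)
    fr <- 1
    for (sb in subs) {
      hs <- harmonicDecompose(sb, energyFraction, maxFreq)
      rng <- sb$start:(sb$start + length(sb$samples) - 1L)
      out[rng, a] <- reconstructSubsignal(hs, derivative = TRUE)
      fr <- min(fr, hs$achieved)
    }
    achieved[a] <- fr
  }
  attr(out, "achieved") <- achieved
  out
}

#' Per-axis eddy field basis of the implant
#'
#' Solves the conservation problem once per coil axis for unit gradient.
#' In the resistive limit the spatial pattern is frequency-independent;
#' every harmonic solution is the pattern scaled by (-j 2 pi f c_k), so the
#' per-voxel current density is J(t) = -sum_axis dG_a/dt * W_a.
#'
#' @param model a \code{TissueModel} with an implant.
#' @param coil a \code{\link{coilModel}}; uniform mode uses the symmetric
#'   gauge potentials of \code{\link{unitVectorPotential}}.
#' @return list: \code{W} list of three (nMetal x 3) field-pattern
#'   matrices (S m / (T/m) units), \code{metalIdx}, \code{sigma},
#'   \code{dim}, \code{spacing}.
#' @export
gradientEddyBasis <- function(model, coil = coilModel()) {
  if (coil$mode != "uniform")
    stop("filamentary basis not implemented; use uniform mode or ",
         "solveEddyHarmonic with an explicit vector potential")
  W <- vector("list", 3)
  pat <- NULL
  for (a in 1:3) {
    pat <- eddyFieldPattern(model, unitVectorPotential(c("x", "y", "z")[a]))
    W[[a]] <- pat$W
  }
  list(W = W, metalIdx = pat$metalIdx, sigma = pat$sigma,
       dim = dim(model@labels), spacing = model@spacing)
}

#' Time-resolved gradient-induced power density
#'
#' Reconstructs the instantaneous volumetric power deposited in the implant
#' by the switched gradients over one representative interval:
#' J(t) = -sum_a dG_a/dt W_a (vector superposition across coil axes before
#' squaring), P(t) = |J(t)|^2 / sigma. Intended for test-scale problems;
#' the thermal pipeline uses the factorised step averages of
#' \code{\link{combinePower}} instead.
#'
#' @param basis from \code{\link{gradientEddyBasis}}.
#' @param timeline a \code{SequenceTimeline}.
#' @param energyFraction,maxFreq harmonic truncation controls.
#' @param tIdx optional subset of sample indices to evaluate.
#' @return matrix (nMetal x length(tIdx)) of power density (W/m^3).
#' @export
reconstructPower <- function(basis, timeline, energyFraction = 0.999,
                             maxFreq = 1e5, tIdx = NULL) {
  gdot <- slewSignals(timeline, energyFraction, maxFreq)
  if (is.null(tIdx)) tIdx <- seq_len(nrow(gdot))
  n <- length(basis$sigma)
  P <- matrix(0, n, length(tIdx))
  for (j in seq_along(tIdx)) {
    Jt <- -(gdot[tIdx[j], 1] * basis$W[[1]] +
            gdot[tIdx[j], 2] * basis$W[[2]] +
            gdot[tIdx[j], 3] * basis$W[[3]])
    P[, j] <- rowSums(Jt^2) / basis$sigma
  }
  P
}
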