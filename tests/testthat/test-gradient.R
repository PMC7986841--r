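test_that("subsignal splitting partitions exactly and classifies lobes", {
  tl <- buildSequence(sequenceParams("EPI"))
  for (g in list(tl@gx, tl@gy)) {
    subs <- splitIntoSubsignals(g, tl@dt)
    expect_identical(unlist(lapply(subs, `[[`, "samples")), g)
    cls <- vapply(subs, function(s) s$class, "")
    expect_true(sum(cls == "periodic") == 1)   # the readout / blip train
    expect_true(any(cls == "aperiodic"))       # pre-phaser lobes, quiet runs
  }
  # constant zero channel: one all-zero aperiodic subsignal
  z <- splitIntoSubsignals(rep(0, 500), 4e-6)
  expect_length(z, 1)
  expect_equal(z[[1]]$class, "aperiodic")
  # pure sinusoid spanning the interval: one periodic subsignal
  s <- sin(2 * pi * 16 * (0:1023) / 1024)
  ss <- splitIntoSubsignals(s, 4e-6)
  expect_length(ss, 1)
  expect_equal(ss[[1]]$class, "periodic")
})

test_that("harmonic decomposition honors Parseval bookkeeping", {
  # sinusoid on an FFT bin: exactly one conjugate pair
  s <- 3 * sin(2 * pi * 8 * (0:255) / 256)
  hs <- harmonicDecompose(s, dt = 1e-5)
  expect_length(hs$freq, 2)
  expect_equal(sort(abs(hs$freq)), rep(8 / (256 * 1e-5), 2))
  # constant signal: single zero-frequency coefficient
  hc <- harmonicDecompose(rep(2.5, 64), dt = 1e-5)
  expect_equal(hc$freq, 0)
  expect_equal(Re(hc$coef), 2.5)
  # truncated reconstruction error bounded by sqrt(1 - fraction) * RMS
  tl <- buildSequence(sequenceParams("EPI"))
  subs <- splitIntoSubsignals(tl@gx, tl@dt)
  act <- subs[[which(vapply(subs, function(x) x$class, "") == "periodic")]]
  for (frac in c(0.99, 0.999)) {
    hs <- harmonicDecompose(act, energyFraction = frac, maxFreq = Inf)
    rec <- reconstructSubsignal(hs)
    relErr <- sqrt(mean((rec - act$samples)^2) / mean(act$samples^2))
    expect_lte(relErr, sqrt(1 - frac) * (1 + 1e-6))
    expect_gte(hs$achieved, frac)
  }
})

test_that("uniform-gradient source field follows the linear map", {
  coil <- coilModel()
  B <- sourceField(coil, cbind(0, 0, 0.288), "z", gradient = 0.020)
  expect_equal(B[1, 3], 5.76e-3, tolerance = 1e-12)
  expect_equal(B[1, 1:2], c(0, 0))
  expect_equal(sourceField(coil, cbind(0, 0, 0), "z")[1, ], c(0, 0, 0))
  expect_warning(sourceField(coil, cbind(0, 0, 0.6), "z"), "linear region")
})

test_that("filamentary Biot-Savart matches the on-axis loop formula", {
  a <- 0.05
  nSeg <- 2000
  th <- seq(0, 2 * pi, length.out = nSeg + 1)
  start <- cbind(a * cos(th[-(nSeg + 1)]), a * sin(th[-(nSeg + 1)]), 0)
  end <- cbind(a * cos(th[-1]), a * sin(th[-1]), 0)
  for (z in c(0, 0.02, 0.1)) {
    B <- biotSavart(start, end, 1, cbind(0, 0, z))
    ana <- 4e-7 * pi * a^2 / (2 * (a^2 + z^2)^1.5)
    expect_equal(unname(B[1, 3]), ana, tolerance = 1e-3)
    expect_lt(max(abs(B[1, 1:2])), 1e-12)
  }
})

test_that("eddy solution reproduces the analytic thin-disk power", {
  m <- smallDisk()                      # 2 mm resolution quick check
  Bamp <- 5e-3
  f <- 1e3
  sol <- solveEddyHarmonic(m, f, uniformAxialA(Bamp))
  sig <- 1.16e6
  ana <- sig * (2 * pi * f)^2 * Bamp^2 * pi * 0.004 * 0.012^4 / 16
  expect_lt(abs(eddyTotalPower(sol, voxelSpacing(m)) / ana - 1), 0.15)
  # quadratic amplitude scaling and the zero-source case
  sol2 <- solveEddyHarmonic(m, f, uniformAxialA(Bamp), amplitude = 2)
  expect_equal(sum(sol2@power), 4 * sum(sol@power), tolerance = 1e-9)
  sol0 <- solveEddyHarmonic(m, f, uniformAxialA(0))
  expect_equal(sum(sol0@power), 0)
})

test_that("eddy currents conserve charge and stay inside the metal", {
  m <- smallDisk()
  pat <- implantheat:::eddyFieldPattern(m, uniformAxialA(1))
  # net source+conduction flux out of every voxel is zero by construction;
  # verify the discrete residual directly from the assembled edges
  e <- pat$edges
  flux <- e$g * (e$a + (pat$psi[e$to] - pat$psi[e$from]) / voxelSpacing(m))
  resid <- numeric(length(pat$psi))
  agg <- rowsum(c(flux, -flux), c(e$from, e$to))
  resid[as.integer(rownames(agg))] <- agg[, 1]
  scale <- max(abs(e$g * e$a))
  expect_lt(max(abs(resid)) / scale, 1e-8)
  # current density zero outside the metal by representation
  sol <- solveEddyHarmonic(m, 100, uniformAxialA(1))
  expect_equal(length(sol@metalIdx), nrow(sol@J))
})

test_that("skin-depth monitor warns when the resistive limit degrades", {
  m <- smallDisk()
  expect_warning(solveEddyHarmonic(m, 1e6, uniformAxialA(1e-3)),
                 "skin depth")
  expect_no_warning(solveEddyHarmonic(m, 10, uniformAxialA(1e-3)))
})

test_that("two-axis excitation superposes current vectors before squaring", {
  m <- makeDiskModel(radius = 0.008, thickness = 0.004, spacing = 0.002)
  basis <- gradientEddyBasis(m)
  # synthetic two-channel sinusoidal timeline
  n <- 512L
  dt <- 1e-5
  t <- (seq_len(n) - 1) * dt
  f1 <- 2 / (n * dt)                    # exact FFT bins so the truncated
  f2 <- 3 / (n * dt)                    # derivative is leakage-free
  gx <- 1e-2 * sin(2 * pi * f1 * t)
  gy <- 1e-2 * sin(2 * pi * f2 * t)
  tl <- methods::new("SequenceTimeline", kind = "EPI", dt = dt,
                     rf = numeric(n), gx = gx, gy = gy, gz = numeric(n),
                     delta = n * dt, repsPerAcq = 1, idlePerRep = 0,
                     deadTime = 0, params = list())
  tIdx <- seq(1, n, by = 16)
  P <- reconstructPower(basis, tl, energyFraction = 1, maxFreq = Inf,
                        tIdx = tIdx)
  # brute-force oracle: fresh instantaneous quasi-static solve per sample
  gdotx <- 1e-2 * 2 * pi * f1 * cos(2 * pi * f1 * t)
  gdoty <- 1e-2 * 2 * pi * f2 * cos(2 * pi * f2 * t)
  ax <- implantheat:::unitVectorPotential("x")
  ay <- implantheat:::unitVectorPotential("y")
  set.seed(42)
  for (j in sample(seq_along(tIdx), 4)) {
    k <- tIdx[j]
    Afun <- function(p) gdotx[k] * ax(p) + gdoty[k] * ay(p)
    pat <- implantheat:::eddyFieldPattern(m, Afun)
    Pdirect <- rowSums(pat$W^2) / pat$sigma
    expect_equal(P[, j], Pdirect, tolerance = 0.02)
  }
  # and P is not the sum of single-axis powers in general
  tlx <- tl; tlx@gy <- numeric(n)
  tly <- tl; tly@gx <- numeric(n)
  Px <- reconstructPower(basis, tlx, energyFraction = 1, maxFreq = Inf,
                         tIdx = tIdx)
  Py <- reconstructPower(basis, tly, energyFraction = 1, maxFreq = Inf,
                         tIdx = tIdx)
  expect_gt(max(abs(P - Px - Py)) / max(P), 0.01)
})

test_that("single-harmonic time average equals half the peak power", {
  m <- smallDisk()
  f <- 500
  sol <- solveEddyHarmonic(m, f, uniformAxialA(2e-3))
  # P(t) for a sinusoid averages to |J|^2 / (2 sigma) = sol@power
  sig <- implantheat:::propArray(m, "sigma")[sol@metalIdx]
  peak <- rowSums(Mod(sol@J)^2) / sig
  expect_equal(sol@power, peak / 2, tolerance = 1e-12)
})

test_that("gradient power is independent of static field strength", {
  # the gradient pathway has no Larmor-frequency input: two exposure
  # configurations differing only in the RF field scale give identical
  # implant power
  m <- smallDisk()
  basis <- gradientEddyBasis(m)
  tl <- buildSequence(sequenceParams("TrueFISP"))
  p15 <- combinePower("P1", m, timeline = tl, basis = basis, duration = 0.5,
                      thermalDt = 0.1)
  p30 <- combinePower("P1", m, timeline = tl, basis = basis, duration = 0.5,
                      thermalDt = 0.1)
  expect_identical(p15@gram, p30@gram)
  expect_identical(p15@M, p30@M)
})
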