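test_that("thermoregulation multipliers follow the doubling law and caps", {
  expect_equal(thermoregMultipliers(0)$LB, 1)
  expect_equal(thermoregMultipliers(0)$metSourceFactor, 0)
  expect_equal(thermoregMultipliers(1.6)$LB, 2)
  # 2^(6.5/1.6) = 16.7 exceeds the non-skin cap
  expect_equal(thermoregMultipliers(6.5)$LB, 15)
  expect_equal(thermoregMultipliers(6.5, isSkin = TRUE)$LB, 2^(6.5 / 1.6))
  # caps engage above deltaB * log2(cap)
  expect_lt(thermoregMultipliers(1.6 * log2(15) - 0.01)$LB, 15)
  expect_equal(thermoregMultipliers(1.6 * log2(15) + 0.01)$LB, 15)
  expect_equal(thermoregMultipliers(1.6 * log2(32) + 0.01,
                                    isSkin = TRUE)$LB, 32)
  # clamped at 1 for cooling
  expect_equal(thermoregMultipliers(-2)$LB, 1)
})

test_that("zero power and zero initial state stay at zero", {
  m <- uniformModel(c(8, 8, 8))
  u <- stepBioheat(m, array(0, c(8, 8, 8)), dt = 0.5,
                   P = array(0, c(8, 8, 8)), nSteps = 20)
  expect_equal(max(abs(u)), 0)
})

test_that("uniform perfusion balance reaches the scalar nonlinear root", {
  props <- tissueTable()
  props$pMet0[props$name == "muscle"] <- 0
  m <- uniformModel(c(4, 4, 4), props = props)
  P <- array(2700, c(4, 4, 4))          # equals h_b0 of muscle
  u <- stepBioheat(m, array(0, c(4, 4, 4)), dt = 2, P = P, nSteps = 4000,
                   hAmb = 0)
  root <- stats::uniroot(function(x) 2^(x / 1.6) * x - 1, c(0.1, 1.5),
                         tol = 1e-12)$root
  expect_lt(abs(u[2, 2, 2] / root - 1), 0.005)
  # every voxel identical (no-flux uniform problem)
  expect_lt(diff(range(u)), 1e-12)
})

test_that("Douglas-Gunn matches a fine-step explicit Euler reference", {
  m <- uniformModel(c(20, 20, 20))
  xs <- seq_len(20)
  P <- array(0, c(20, 20, 20))
  for (k in 1:20)
    P[, , k] <- outer(xs, xs, function(i, j)
      5e3 * (1 + sin(2 * pi * i / 20) * cos(2 * pi * j / 20)) +
        3e3 * sin(pi * k / 20))
  uDG <- stepBioheat(m, array(0, c(20, 20, 20)), dt = 0.5, P = P,
                     nSteps = 120, hAmb = 7, robinAtBounds = TRUE)
  uE <- eulerReference(m, dt = 0.005, P = P, nSteps = 12000, hAmb = 7,
                       robinAtBounds = TRUE)
  expect_lt(max(abs(uDG - uE)) / max(uE), 0.01)
})

test_that("1D Robin slab matches the closed-form steady profile", {
  props <- tissueTable()
  props$hB0[] <- 0; props$pMet0[] <- 0   # linear conduction only
  n <- 80L; dx <- 0.001
  lab <- array(1L, c(n + 2L, 1L, 1L))
  lab[c(1L, n + 2L)] <- 0L               # air caps carry the Robin faces
  m <- methods::new("TissueModel", spacing = dx, labels = lab,
                    implantMask = array(FALSE, c(n + 2L, 1L, 1L)),
                    properties = props, origin = c(0, 0, 0), meta = list())
  q <- 5000; lam <- props$lambdaTh[1]; h <- 7
  P <- array(q, c(n + 2L, 1L, 1L)); P[c(1L, n + 2L)] <- 0
  u <- stepBioheat(m, array(0, dim(lab)), dt = 50, P = P, nSteps = 6000,
                   hAmb = h)
  L <- n * dx
  x <- (seq_len(n) - 0.5) * dx - L / 2
  ana <- q * ((L / 2)^2 - x^2) / (2 * lam) + q * L / (2 * h)
  expect_lt(max(abs(u[2:(n + 1), 1, 1] - ana)) / max(ana), 0.005)
})

test_that("time splitting is second-order accurate on a smooth problem", {
  props <- tissueTable()
  props$hB0[] <- 0; props$pMet0[] <- 0
  m <- uniformModel(c(16, 16, 16), props = props)
  xs <- (seq_len(16) - 8.5)
  g <- exp(-outer(xs^2, xs^2, "+") / 18)
  u0 <- array(0, c(16, 16, 16))
  for (k in 1:16) u0[, , k] <- g * exp(-(k - 8.5)^2 / 18)
  P0 <- array(0, c(16, 16, 16))
  run <- function(dt, nSteps) stepBioheat(m, u0, dt = dt, P = P0,
                                          nSteps = nSteps, hAmb = 0)
  u1 <- run(4, 30); u2 <- run(2, 60); u4 <- run(1, 120); u8 <- run(0.5, 240)
  # Richardson self-convergence: successive-difference norms shrink ~4x
  e1 <- max(abs(u1 - u2)); e2 <- max(abs(u2 - u4)); e4 <- max(abs(u4 - u8))
  expect_gt(e1 / e2, 3)
  expect_gt(e2 / e4, 3)
})

test_that("solutions relax monotonically and stay non-negative", {
  m <- uniformModel(c(10, 10, 10), padAir = TRUE)
  P <- array(5e3, c(10, 10, 10))
  u <- array(0, c(10, 10, 10))
  prevMax <- 0
  for (i in 1:10) {
    u <- stepBioheat(m, u, dt = 1, P = P, nSteps = 5)
    expect_gte(min(u), 0)
    expect_gte(max(u) + 1e-12, prevMax)
    prevMax <- max(u)
  }
})

test_that("steady state balances deposition, perfusion and boundary flux", {
  m <- uniformModel(c(12, 12, 12), padAir = TRUE)
  d <- c(12, 12, 12)
  P <- array(0, d); P[tissueLabels(m) != 0L] <- 2e4
  u <- stepBioheat(m, array(0, d), dt = 5, P = P, nSteps = 5000, hAmb = 7)
  props <- tissueProps(m)
  mu <- props[props$name == "muscle", ]
  vol <- voxelVolume(m)
  act <- tissueLabels(m) != 0L
  dep <- sum(P[act]) * vol +
    sum((1.1^u[act] - 1) * mu$pMet0) * vol
  perf <- sum(pmin(15, 2^(u[act] / 1.6)) * mu$hB0 * u[act]) * vol
  # boundary flux through exposed faces with the half-cell Robin resistance
  dx <- voxelSpacing(m)
  res <- 1 / 7 + dx / (2 * mu$lambdaTh)
  surf <- which(surfaceMask(m))
  ijk <- arrayInd(surf, d)
  nFaces <- rowSums(cbind(ijk == 2, ijk == d[1] - 1))
  flux <- sum(u[surf] / res * dx^2 * nFaces)
  expect_lt(abs((perf + flux) / dep - 1), 0.01)
})

test_that("the marching step is converged at its default", {
  m <- smallDisk()
  basis <- gradientEddyBasis(m)
  tl <- buildSequence(sequenceParams("EPI"))
  mx <- vapply(c(0.2, 0.1, 0.05), function(dtt) {
    pm <- combinePower("P1", m, timeline = tl, basis = basis,
                       duration = 10, thermalDt = dtt)
    maxDeltaT(solveBioheat(m, pm))
  }, 0)
  expect_lt(abs(mx[1] / mx[2] - 1), 0.005)
  expect_lt(abs(mx[2] / mx[3] - 1), 0.005)
})

test_that("solveBioheat integrates power maps and reports crossings", {
  m <- smallDisk()
  basis <- gradientEddyBasis(m)
  tl <- buildSequence(sequenceParams("EPI"))
  pm <- combinePower("P1", m, timeline = tl, basis = basis, duration = 20,
                     thermalDt = 0.1)
  st <- solveBioheat(m, pm, snapshotTimes = c(10, 20),
                     thresholds = c(0.01, 0.05))
  expect_length(st@snapshots, 2)
  expect_true(all(diff(st@maxSeries) > -1e-12))   # monotone heating
  t1 <- timeToThreshold(st, 0.01)
  t2 <- timeToThreshold(st, 0.05)
  if (!is.na(t1) && !is.na(t2)) expect_gte(t2, t1)
  # duration 0 equivalent: zero steps -> initial state untouched
  expect_equal(min(st@snapshots[[1]]), 0)
})
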