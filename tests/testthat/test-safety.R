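mkState <- function(u, dt = 0.1) {
  methods::new("ThermalState", snapshots = list(u),
               snapshotTimes = 1, maxSeries = max(u), times = 1,
               crossTimes = matrix(NA_real_, 0, 0), thresholds = numeric(0),
               dim = as.integer(dim(u)))
}

test_that("maximum temperature increase respects masks", {
  u <- array(0, c(5, 5, 5))
  st <- mkState(u)
  expect_equal(maxDeltaT(st), 0)
  u[3, 3, 3] <- 2.5
  st <- mkState(u)
  expect_equal(maxDeltaT(st), 2.5)
  mask <- array(FALSE, c(5, 5, 5)); mask[1, 1, 1] <- TRUE
  expect_equal(maxDeltaT(st, mask), 0)
  expect_gte(maxDeltaT(st), maxDeltaT(st, mask))  # subset monotonicity
  expect_error(maxDeltaT(st, array(FALSE, c(5, 5, 5))), "empty mask")
})

test_that("heated mass sums rho times voxel volume per tissue", {
  ph <- smallPhantom()
  d <- dim(tissueLabels(ph))
  u <- array(0, d)
  muscleIdx <- which(tissueLabels(ph) ==
                     tissueProps(ph)$label[tissueProps(ph)$name == "muscle"])
  u[muscleIdx[1:3]] <- 1.5
  st <- mkState(u)
  g <- massAboveThreshold(st, ph, 1)
  expect_equal(unname(g["muscle"]), 3 * 8e-9 * 1090 * 1e3,
               tolerance = 1e-12)               # 0.02616 g
  expect_equal(unname(g["fat"]), 0)
  # monotone in threshold
  g3 <- massAboveThreshold(st, ph, 3)
  expect_true(all(g3 <= g))
  # implant voxels never counted
  u2 <- array(0, d); u2[metalIndices(ph)] <- 10
  expect_equal(unname(massAboveThreshold(mkState(u2), ph, 1)["total"]), 0)
})

test_that("time-to-threshold interpolates between marching steps", {
  times <- (1:5) * 0.1
  series <- c(0.2, 0.5, 1.0, 1.4, 1.8)
  # exact hit at a step
  expect_equal(timeToThreshold(series, 0.5 - 1e-12, times = times), 0.2,
               tolerance = 1e-9)
  # crossing between steps: hand-computed linear interpolation
  # between t=0.3 (1.0) and t=0.4 (1.4): 1.2 is reached at 0.35
  expect_equal(timeToThreshold(series, 1.2, times = times), 0.35,
               tolerance = 1e-12)
  # never crossing
  expect_true(is.na(timeToThreshold(series, 5, times = times)))
  # 3 K crossing cannot precede the 1 K crossing
  t1 <- timeToThreshold(series, 0.4, times = times)
  t3 <- timeToThreshold(series, 1.5, times = times)
  expect_gte(t3, t1)
})

test_that("distance transform matches brute force on a toy grid", {
  set.seed(11)
  d <- c(20L, 20L, 20L)
  props <- tissueTable()
  lab <- array(labelOf_(props, "muscle"), d)
  mask <- array(FALSE, d)
  seeds <- cbind(sample(5:15, 6, TRUE), sample(5:15, 6, TRUE),
                 sample(5:15, 6, TRUE))
  mask[seeds] <- TRUE
  lab[mask] <- labelOf_(props, "cocrmo")
  m <- methods::new("TissueModel", spacing = 0.002, labels = lab,
                    implantMask = mask, properties = props,
                    origin = c(0, 0, 0), meta = list())
  dist <- distanceToImplant(m)
  # brute force over all voxels vs all surface (= all seed) voxels
  allIjk <- arrayInd(seq_len(prod(d)), d)
  sIjk <- arrayInd(which(mask), d)
  brute <- apply(allIjk, 1, function(p)
    sqrt(min(colSums((t(sIjk) - p)^2))) * 0.002)
  expect_equal(as.numeric(dist), brute, tolerance = 1e-12)
  # zero exactly on the surface voxels, positive elsewhere
  expect_true(all(dist[mask] == 0))
  expect_true(all(dist[!mask] > 0))
})

test_that("implant-adjacent voxels sit one voxel spacing away", {
  ph <- smallPhantom()
  dist <- distanceToImplant(ph)
  d <- dim(dist)
  surf <- implantheat:::implantSurfaceMask(ph)
  idx <- which(surf)[1]
  ijk <- arrayInd(idx, d)
  # walk outward along +x until leaving the implant
  i <- ijk[1]
  while (implantMask(ph)[i, ijk[2], ijk[3]]) i <- i + 1L
  expect_equal(dist[i, ijk[2], ijk[3]], voxelSpacing(ph))
})

test_that("region of influence contains the implant bounding box", {
  ph <- smallPhantom()
  roi <- regionOfInfluence(ph)
  expect_true(all(roi[implantMask(ph)]))
  expect_error(regionOfInfluence(ph, size = c(0.01, 0.01, 0.01)),
               "smaller than the implant")
  expect_error(regionOfInfluence(makePhantom(shape = c(20L, 20L, 20L),
                                             spec = NULL, radius = 0.017,
                                             boneRadius = 0.002,
                                             layers = c(skin = 0.002))),
               "no implant")
})

test_that("distance profile reports tissue, distance and heating", {
  ph <- smallPhantom()
  d <- dim(tissueLabels(ph))
  u <- array(0.5, d)
  st <- mkState(u)
  prof <- distanceProfile(st, ph, region = regionOfInfluence(ph))
  expect_true(all(prof$distance >= voxelSpacing(ph) - 1e-12))
  expect_true(all(prof$deltaT == 0.5))
  expect_true(all(prof$tissue %in% tissueProps(ph)$name))
  expect_false(any(prof$tissue %in% c("cocrmo", "pe")))
})

test_that("safety report assembles its parts consistently", {
  m <- smallDisk()
  basis <- gradientEddyBasis(m)
  tl <- buildSequence(sequenceParams("EPI"))
  pm <- combinePower("P1", m, timeline = tl, basis = basis, duration = 10,
                     thermalDt = 0.1)
  st <- solveBioheat(m, pm, snapshotTimes = c(5, 10),
                     thresholds = c(0.005, 0.02))
  rep <- safetyReport(st, m, thresholds = c(0.005, 0.02))
  expect_length(rep$maxDeltaT, 2)
  expect_true(all(rep$maxDeltaT >= rep$maxDeltaTRegion - 1e-12))
  expect_true(all(rep$heatedMass[["0.005K"]] >=
                  rep$heatedMass[["0.02K"]]))
  if (!any(is.na(rep$timeToThreshold)))
    expect_gte(rep$timeToThreshold["0.02K"],
               rep$timeToThreshold["0.005K"])
  out <- file.path(tempdir(), "report.json")
  writeSafetyReport(rep, out)
  expect_true(file.exists(out))
})
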