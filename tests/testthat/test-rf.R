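test_that("synthetic deposition follows the sigma r^2 law", {
  ph <- makePhantom(shape = c(100L, 100L, 60L), spec = NULL)
  map <- syntheticRFMap(ph)
  d <- dim(map@P)
  kz <- d[3] %/% 2
  ctr <- d[1] %/% 2                      # bore axis runs through the centre
  # on-axis voxel: r ~ spacing/2, essentially zero deposition
  expect_lt(map@P[ctr, ctr, kz], map@P[ctr + 20, ctr, kz] / 100)
  # same tissue at r and 2r inside the footprint: ratio 1:4
  lab <- tissueLabels(ph)
  x <- voxelCenters(ph, 1)
  yc <- voxelCenters(ph, 2)[ctr]
  i1 <- which.min(abs(x - 0.03)); i2 <- which.min(abs(x - 0.06))
  expect_equal(lab[i1, ctr, kz], lab[i2, ctr, kz])  # both muscle
  expect_equal(map@P[i2, ctr, kz] / map@P[i1, ctr, kz],
               (x[i2]^2 + yc^2) / (x[i1]^2 + yc^2), tolerance = 1e-9)
  expect_true(all(map@P >= 0))
})

test_that("deposition vanishes when the body sits far outside the coil", {
  ph <- smallPhantom()
  centred <- rfTotalPower(syntheticRFMap(ph), ph)
  far <- ph
  far@origin[3] <- 0.7                  # fully beyond footprint + roll-off
  expect_lt(rfTotalPower(syntheticRFMap(far), far), 0.05 * centred)
})

test_that("PEC masking zeroes the metal and is idempotent", {
  ph <- smallPhantom()
  map <- syntheticRFMap(ph)
  expect_true(all(map@P[metalIndices(ph)] == 0))
  once <- pecMask(map, ph)
  twice <- pecMask(once, ph)
  expect_identical(once@P, twice@P)
})

test_that("whole-body SAR follows its definition and is linear", {
  ph <- smallPhantom()
  # uniform P = 2 rho over all tissue gives exactly 2 W/kg
  rho <- implantheat:::propArray(ph, "rho")
  map <- methods::new("RFPowerMap", P = 2 * rho,
                      referenceB1sq = 1, footprint = c(-0.225, 0.225),
                      meta = list())
  sar <- sarWb(map, ph)
  # PEC masking removes the implant contribution from the numerator only
  metalMass <- sum(rho[metalIndices(ph)]) * voxelVolume(ph)
  expected <- 2 * (modelMass(ph) - metalMass) / modelMass(ph)
  expect_equal(sar, expected, tolerance = 1e-9)
  # zero map, and linear scaling
  zero <- map; zero@P[] <- 0
  expect_equal(sarWb(zero, ph), 0)
  k3 <- map; k3@P <- 3 * map@P
  expect_equal(sarWb(k3, ph), 3 * sar, tolerance = 1e-12)
})

test_that("sequence scaling is linear in mean-square B1", {
  ph <- smallPhantom()
  map <- syntheticRFMap(ph)
  same <- scaleToSequence(map, map@referenceB1sq)
  expect_equal(same@P, map@P)
  # dead time dilutes the map proportionally
  tl <- buildSequence(sequenceParams("TrueFISP"))
  b <- rfMeanSquareB1(tl)
  tlDead <- tl; tlDead@deadTime <- acquisitionDuration(tl)  # 50% duty
  s1 <- scaleToSequence(map, b)
  s2 <- scaleToSequence(map, rfMeanSquareB1(tlDead))
  expect_equal(s2@P, s1@P / 2, tolerance = 1e-9)
})

test_that("dead time closes the SAR loop at exactly the limit", {
  ph <- smallPhantom()
  tl <- buildSequence(sequenceParams("TSE"))
  map <- syntheticRFMap(ph)
  sar0 <- sarWb(scaleToSequence(map, rfMeanSquareB1(tl)), ph)
  # scale the reference so the uninterrupted sequence lands above 2 W/kg
  boost <- 5 / sar0
  hot <- map; hot@P <- hot@P * boost
  sarHot <- sarWb(scaleToSequence(hot, rfMeanSquareB1(tl)), ph)
  dtc <- deadTimeForSAR(sarHot, acquisitionDuration(tl))
  tl@deadTime <- dtc
  expect_equal(sarWb(scaleToSequence(hot, rfMeanSquareB1(tl)), ph), 2,
               tolerance = 1e-6)
})

test_that("imported maps are conservatively remapped", {
  ph <- makePhantom(shape = c(24L, 24L, 30L), spec = NULL,
                    layers = c(skin = 0.002), boneRadius = 0.004,
                    radius = 0.020)
  # identity remap
  P <- array(runif(prod(dim(tissueLabels(ph)))), dim(tissueLabels(ph)))
  f <- file.path(tempdir(), "rfmap.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(P), f)
  imp <- importRFMap(f, ph)
  expect_equal(imp@P, pecMask(methods::new("RFPowerMap", P = P,
               referenceB1sq = 1, footprint = c(-0.225, 0.225),
               meta = list()), ph)@P, tolerance = 1e-6)
  # 1 mm -> 2 mm downsampling conserves the total power of a uniform map
  fine <- array(7.5, dim(tissueLabels(ph)) * 2L)
  f2 <- file.path(tempdir(), "rfmap_fine.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(fine), f2)
  imp2 <- importRFMap(f2, ph)
  totFine <- sum(fine) * (voxelSpacing(ph) / 2)^3
  totCoarse <- sum(imp2@P) * voxelVolume(ph)
  expect_lt(abs(totCoarse / totFine - 1), 0.001)
  # negative values rejected; mismatched grids rejected
  bad <- array(-1, dim(tissueLabels(ph)))
  f3 <- file.path(tempdir(), "rfmap_bad.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(bad), f3)
  expect_error(importRFMap(f3, ph), "negative")
  odd <- array(1, dim(tissueLabels(ph)) + 1L)
  f4 <- file.path(tempdir(), "rfmap_odd.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(odd), f4)
  expect_error(importRFMap(f4, ph), "mismatch")
})
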