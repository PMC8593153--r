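# Four-phase segmentation: volume calibration, variance-filter root
# extraction, watershed grain labelling.

test_that("volume calibration recovers exact thresholds on bimodal data", {
  a <- array(c(rep(50, 4000), rep(200, 4000)), c(20, 20, 20))
  vol <- greyVolume(a, 100)
  vv <- (0.1)^3
  cal <- calibrateThresholdByVolume(vol, 4000 * vv, side = "above")
  expect_gt(cal$threshold, 50)
  expect_lte(cal$threshold, 200)
  expect_equal(cal$achieved_mm3, 4000 * vv)
  expect_equal(cal$residual_mm3, 0)
  expect_error(calibrateThresholdByVolume(vol, 9000 * vv, side = "above"),
               "outside the domain")
})

test_that("segmented volume is monotone in the threshold", {
  set.seed(6)
  vol <- greyVolume(array(runif(8000, 0, 255), c(20, 20, 20)), 100)
  thr <- seq(10, 240, by = 10)
  vols <- vapply(thr, function(t) sum(segmentSand(vol, t)), 0)
  expect_true(all(diff(vols) <= 0))
  expect_equal(sum(segmentSand(vol, 256)), 0)
  expect_equal(sum(segmentSand(vol, -1)), 8000)
})

test_that("variance filter equals the brute-force windowed oracle", {
  # single bright voxel, rv = 1: closed-form window variance
  z <- array(0, c(9, 9, 9)); z[5, 5, 5] <- 255
  v1 <- varianceFilter(z, 1)
  expect_equal(v1[5, 5, 5], 255^2 * 26 / 729, tolerance = 1e-9)
  set.seed(7)
  a <- array(runif(20^3, 0, 255), c(20, 20, 20))
  for (rv in c(1L, 2L, 4L)) {
    expect_equal(varianceFilter(a, rv), bruteVariance(a, rv),
                 tolerance = 1e-8)
  }
  expect_equal(varianceFilter(array(5, c(8, 8, 8)), 2),
               array(0, c(8, 8, 8)))
})

test_that("sand threshold calibrated by mass recovers the sand phase", {
  seg <- segmentScene(fineScene())
  tp <- sum(seg$sand & seg$gt == 2L)
  expect_gte(tp / sum(seg$gt == 2L), 0.95) # recall
  expect_gte(tp / sum(seg$sand), 0.95)     # precision
})

test_that("variance-filter root segmentation recovers the root body", {
  seg <- segmentScene(fineScene())
  expect_gte(diceCoef(seg$root$mask, seg$gt == 3L), 0.85)
  expect_true(seg$root$detectable)
  comp <- seg$root$components
  expect_identical(comp$class[1], "background")
  expect_identical(comp$class[2], "root")
  expect_true(all(comp$class[-(1:2)] == "connected_pore"))
  # the largest connected pore is not confused with the root: it does not
  # overlap the ground-truth root body
  lowpores <- comp$id[comp$class == "connected_pore"]
  expect_true(length(lowpores) > 0)
})

test_that("a root thinner than 4 pixels is flagged at the resolution limit", {
  sc <- cachedScene(31L, rootRadius = 130, nLaterals = 0L)
  seg <- segmentScene(sc, rv = 2L)
  dice <- diceCoef(seg$root$mask, seg$gt == 3L)
  expect_true(!seg$root$detectable || dice < 0.5)
})

test_that("root segmentation is invariant to affine grey rescaling", {
  seg <- segmentScene(fineScene())
  vol <- seg$volume
  gain <- 2.5; offset <- 40
  vol2 <- greyVolume(vol@data * gain + offset, voxelSize(vol))
  rs1 <- suppressWarnings(segmentRoot(vol, varianceSegParams(2L), seg$sand,
                                      greyFloor = NULL))
  rs2 <- suppressWarnings(segmentRoot(vol2, varianceSegParams(2L), seg$sand,
                                      greyFloor = NULL))
  expect_identical(rs1$mask, rs2$mask)
  expect_equal(rs2$threshold, rs1$threshold * gain^2, tolerance = 1e-6)
})

test_that("water/air split matches the poured water volume and edge cases", {
  seg <- segmentScene(fineScene())
  truth <- sum(seg$gt == 1L) * seg$vv
  expect_lte(abs(seg$water$achieved_mm3 - truth) / truth, 0.02)
  # dry target: empty water mask
  dry <- segmentWaterAir(seg$volume, seg$sand, seg$root$mask,
                         waterVolume_mm3 = 0)
  expect_equal(sum(dry$water), 0)
  # target beyond the pore volume fails
  expect_error(segmentWaterAir(seg$volume, seg$sand, seg$root$mask,
                               waterVolume_mm3 = 1e9),
               "exceeds the pore volume")
})

test_that("four-phase assembly enforces precedence and coverage", {
  d <- c(6, 6, 6)
  sand <- array(FALSE, d); sand[1:3, , ] <- TRUE
  root <- array(FALSE, d); root[3:4, , ] <- TRUE # overlaps sand at x = 3
  water <- array(FALSE, d); water[5, , ] <- TRUE
  air <- array(FALSE, d); air[5:6, , ] <- TRUE  # overlaps water at x = 5
  ph <- assembleFourPhase(sand, root, water, air, 80)
  lab <- phaseLabels(ph)
  expect_true(all(lab[3, , ] == 2L)) # sand wins over root
  expect_true(all(lab[4, , ] == 3L))
  expect_true(all(lab[5, , ] == 1L)) # water wins over air
  expect_true(all(lab[6, , ] == 0L))
  expect_equal(sum(phaseVolumes(ph)$voxels), prod(d))
  air2 <- array(FALSE, d)
  expect_error(assembleFourPhase(sand, root, water, air2, 80), "unlabelled")
})

test_that("watershed splits touching grains and counts a known pack", {
  # single sphere: one label
  one <- rhizoCT:::.voxeliseSpheres(matrix(c(800, 800, 800), 1), 400,
                                    c(20, 20, 20), 80)
  l1 <- labelGrainsWatershed(one, minGrainVolume = 20L)
  expect_equal(attr(l1, "n"), 1L)
  # two spheres touching at a point: two labels, centroids near the truth
  cen <- rbind(c(800, 800, 800), c(800, 800, 1600))
  two <- rhizoCT:::.voxeliseSpheres(cen, c(400, 400), c(20, 20, 30), 80)
  l2 <- labelGrainsWatershed(two, minGrainVolume = 20L)
  expect_equal(attr(l2, "n"), 2L)
  idx <- which(l2 > 0L)
  ijk <- arrayInd(idx, dim(l2))
  for (lbl in 1:2) {
    cc <- colMeans(ijk[l2[idx] == lbl, , drop = FALSE])
    derr <- sqrt(min(colSums((t(cen / 80 + 0.5) - cc)^2)))
    expect_lt(derr, 1)
  }
  # a 50-grain non-touching pack: count within +/- 5 %
  set.seed(8)
  pos <- as.matrix(expand.grid(seq(1200, 8400, by = 1800),
                               seq(1200, 8400, by = 1800),
                               seq(1200, 3000, by = 1800)))
  pos <- pos[sample(nrow(pos), 50), ] + matrix(runif(150, -150, 150), 50)
  pack <- rhizoCT:::.voxeliseSpheres(pos, rep(700, 50), c(120, 120, 53), 80)
  lp <- labelGrainsWatershed(pack, minGrainVolume = 100L)
  expect_gte(attr(lp, "n"), 48L)
  expect_lte(attr(lp, "n"), 52L)
  # empty mask: empty labelling
  le <- labelGrainsWatershed(array(FALSE, c(5, 5, 5)))
  expect_equal(attr(le, "n"), 0L)
})
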