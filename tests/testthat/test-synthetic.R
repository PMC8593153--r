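# Synthetic scene generator: porosity control, root geometry, rendering,
# prescribed warps.

test_that("grain packs hit the target porosity of both study densities", {
  loose <- generateGrainPack(sceneConfig(targetPorosity = 0.475, rngSeed = 1L))
  expect_gte(loose$porosity, 0.465)
  expect_lte(loose$porosity, 0.485)
  dense <- generateGrainPack(sceneConfig(targetPorosity = 0.43,
                                         relativeDensity = 0.79, rngSeed = 2L))
  expect_gte(dense$porosity, 0.42)
  expect_lte(dense$porosity, 0.44)
  # spheres never overlap
  g <- loose$grains[loose$grains$kept, ]
  n <- nrow(g)
  sub <- g[sample.int(n, min(n, 300)), ]
  dd <- as.matrix(dist(sub[, c("x", "y", "z")]))
  rr <- outer(sub$r, sub$r, "+")
  diag(dd) <- Inf
  expect_true(all(dd >= rr - 1e-6))
})

test_that("an unreachable target porosity fails with the achievable range", {
  cfg <- sceneConfig(targetPorosity = 0.25, porosityBounds = c(0.2, 0.51),
                     rngSeed = 1L)
  expect_error(generateGrainPack(cfg), "achievable porosity range")
})

test_that("identical configurations generate identical scenes", {
  cfg <- sceneConfig(cellWidth = 4.0, cellHeight = 4.8, headspace = 0.8,
                     nLaterals = 1L, rngSeed = 7L)
  a <- synthScene(cfg)
  b <- synthScene(cfg)
  expect_identical(a@volume@data, b@volume@data)
  expect_identical(a@grains, b@grains)
  expect_identical(phaseLabels(a@phases), phaseLabels(b@phases))
})

test_that("root systems have the requested topology and taper", {
  cfg0 <- sceneConfig(nLaterals = 0L, tortuosity = 0, rngSeed = 3L)
  r0 <- generateRootSystem(cfg0)
  br0 <- branches(r0$skeleton)
  expect_equal(nrow(br0), 1L)
  nd <- skeletonNodes(r0$skeleton)
  # straight vertical primary: x/y stay at the seed position
  expect_lt(max(abs(nd$x - nd$x[1])), 1e-9)
  expect_lt(max(abs(nd$y - nd$y[1])), 1e-9)
  # taper: per-node radius monotone non-increasing toward the tip
  expect_true(all(diff(nd$radius_um) <= 1e-9))
  # the voxelised tube contains the exact centreline
  iv <- cbind(round(nd$x), round(nd$y), round(nd$z))
  expect_true(all(r0$mask[iv]))

  cfg3 <- sceneConfig(nLaterals = 3L, rngSeed = 3L)
  r3 <- generateRootSystem(cfg3)
  br3 <- branches(r3$skeleton)
  expect_equal(sum(br3$order == 1L), 1L)
  expect_equal(sum(br3$order == 2L), 3L)
})

test_that("rendered scenes conserve phase volumes and honour grey means", {
  cfg <- sceneConfig(cellWidth = 4.0, cellHeight = 4.8, headspace = 0.8,
                     noiseSigma = 0, psfSigma = 0, rngSeed = 4L)
  sc <- synthScene(cfg)
  pv <- phaseVolumes(sc@phases)
  expect_equal(sum(pv$voxels), prod(dim(phaseLabels(sc@phases))))
  # noiseless, PSF-free render: exactly one grey value per phase
  expect_lte(length(unique(as.vector(sc@volume@data))), 4L)
  gm <- sort(unname(cfg@greyMeans))
  expect_true(all(unique(as.vector(sc@volume@data)) %in% gm))
  # dry scene: no water phase
  dry <- synthScene(sceneConfig(cellWidth = 4.0, cellHeight = 4.8,
                                headspace = 0.8, waterTableDepth = Inf,
                                capillaryFringe = 0, rngSeed = 4L))
  expect_equal(phaseVolumes(dry@phases)$voxels[2], 0L)
})

test_that("translation warp equals a rolled volume in the interior", {
  sc <- fineScene()
  ref <- sc@volume
  w <- warpScene(ref, "translation", list(t = c(3, -2, 1)))
  rolled <- rollArray(ref@data, c(3, -2, 1))
  d <- dim(ref@data)
  i <- 6:(d[1] - 5); j <- 6:(d[2] - 5); k <- 6:(d[3] - 5)
  expect_equal(w$deformed@data[i, j, k], rolled[i, j, k], tolerance = 1e-12)
})

test_that("warp evaluators return the closed-form field", {
  sc <- fineScene()
  d <- dim(sc@volume@data)
  # affine: eps_v of uniform 1% stretch is the determinant identity
  w <- warpScene(sc@volume, "affine", list(F = 1.01 * diag(3)))
  F <- w$gradient(matrix(c(10, 20, 30), 1))[1, , ]
  expect_equal(det(F) - 1, 0.030301, tolerance = 1e-12)
  # radial: sampled displacements match u_r = a exp(-r / lambda)
  a0 <- 1.5; lam <- 12
  wr <- warpScene(sc@volume, "radial",
                  list(a = a0, lambda = lam, axis = c(30, 40)))
  pts <- cbind(runif(50, 5, d[1] - 5), runif(50, 5, d[2] - 5),
               runif(50, 5, d[3] - 5))
  u <- wr$displacement(pts)
  r <- sqrt((pts[, 1] - 30)^2 + (pts[, 2] - 40)^2)
  expect_equal(sqrt(rowSums(u^2)), a0 * exp(-r / lam), tolerance = 1e-9)
  expect_equal(u[, 3], rep(0, 50))
})

test_that("warping by F then F^-1 restores a smooth volume", {
  sc <- fineScene()
  smooth <- greyVolume(gaussianBlur3d(sc@volume@data, 1.5), 80)
  F0 <- 1.01 * diag(3); F0[1, 3] <- 0.004
  w1 <- warpScene(smooth, "affine", list(F = F0))
  w2 <- warpScene(w1$deformed, "affine", list(F = solve(F0)))
  d <- dim(smooth@data)
  i <- 11:(d[1] - 10); j <- 11:(d[2] - 10); k <- 11:(d[3] - 10)
  rms <- sqrt(mean((smooth@data[i, j, k] - w2$deformed@data[i, j, k])^2))
  expect_lt(rms, 2)
})
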