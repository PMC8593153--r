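# DIC, particle tracking, strain estimation and invariants.

test_that("local DIC recovers integer shifts exactly and flags flat windows", {
  sc <- fineScene()
  ref <- sc@volume
  def <- greyVolume(rollArray(ref@data, c(3, -2, 1)), voxelSize(ref), 1L)
  fld <- localDIC(ref, def, windowSide_mm = 1.3, searchRadius_vox = 4)
  ok <- fld@status == "converged"
  expect_gt(sum(ok), 20)
  u <- fld@displacements[ok, , drop = FALSE] / (voxelSize(ref) * 1e-3)
  expect_equal(max(abs(sweep(u, 2, c(3, -2, 1)))), 0)
  # constant volume: every window is poor correlation or out of bounds
  cv <- greyVolume(array(100, c(40, 40, 40)), 80)
  fl <- localDIC(cv, cv, windowSide_mm = 1.3)
  expect_true(all(fl@status != "converged"))
})

test_that("sub-voxel shifts are recovered to a tenth of a voxel", {
  sc <- fineScene()
  ref <- sc@volume
  w <- warpScene(ref, "translation", list(t = c(0.5, 0.5, 0.5)))
  fld <- localDIC(ref, w$deformed, windowSide_mm = 1.3, searchRadius_vox = 3)
  ok <- fld@status == "converged"
  u <- fld@displacements[ok, , drop = FALSE] / (voxelSize(ref) * 1e-3)
  err <- sqrt(rowSums(sweep(u, 2, c(0.5, 0.5, 0.5))^2))
  expect_lte(mean(err), 0.1)
})

test_that("particle tracking matches translated grain labels exactly", {
  cen <- as.matrix(expand.grid(seq(800, 4000, by = 1600),
                               seq(800, 4000, by = 1600),
                               seq(800, 4000, by = 1600)))
  lab <- labelComponents(
    rhizoCT:::.voxeliseSpheres(cen, rep(500, nrow(cen)), c(60, 60, 60), 80))
  lab2 <- array(0L, dim(lab))
  lab2[4:60, , ] <- lab[1:57, , ]
  tr <- trackParticles(lab, lab2, 80, maxDisp_mm = 0.6)
  # interior grains (not clipped by the shift) match the translation exactly
  ok <- tr@status == "converged" & tr@points[, 1] > 0.8
  expect_gt(sum(ok), 10)
  u <- tr@displacements[ok, , drop = FALSE] / 0.08
  expect_lt(max(abs(sweep(u, 2, c(3, 0, 0)))), 1e-9)
  # a deleted grain is flagged unmatched, others unaffected
  lab3 <- lab
  lab3[lab3 == lab[30, 30, 30]] <- 0L
  tr2 <- trackParticles(lab, lab3, 80, maxDisp_mm = 0.3)
  expect_equal(sum(tr2@status == "unmatched"), 1L)
})

test_that("tracking error stays below 0.3 voxel under sub-voxel jitter", {
  set.seed(13)
  cen <- as.matrix(expand.grid(seq(800, 6000, by = 1300),
                               seq(800, 6000, by = 1300),
                               seq(800, 6000, by = 1300)))
  r <- rep(450, nrow(cen))
  jit <- matrix(rnorm(length(cen), 0, 0.2 * 80), nrow(cen))
  labA <- labelComponents(rhizoCT:::.voxeliseSpheres(cen, r, c(85, 85, 85), 80))
  labB <- labelComponents(rhizoCT:::.voxeliseSpheres(cen + jit, r,
                                                     c(85, 85, 85), 80))
  tr <- trackParticles(labA, labB, 80, maxDisp_mm = 0.5)
  ok <- tr@status == "converged"
  u <- tr@displacements[ok, , drop = FALSE] / 0.08
  terr <- u - jit[ok, , drop = FALSE] / 80
  expect_lte(sqrt(mean(terr^2)), 0.3)
})

test_that("grid strain is exact on affine fields and masks thin support", {
  set.seed(14)
  grid <- as.matrix(expand.grid(1:6, 1:6, 1:6)) * 1.3
  F0 <- diag(3) + matrix(c(0.01, 0.003, 0, -0.002, 0.005, 0.001,
                           0, 0.002, -0.004), 3, 3)
  u <- sweep(grid, 2, colMeans(grid)) %*% t(F0 - diag(3))
  fld <- new("DisplacementField", points = grid, displacements = u,
             status = rep("converged", nrow(grid)), windowSide = 1.3,
             quality = rep(1, nrow(grid)))
  st <- strainGeers(fld)
  expect_true(all(st@valid))
  err <- max(abs(sweep(st@F, c(2, 3), F0)))
  expect_lt(err, 1e-10)
  # fewer than 4 neighbours: masked, not an error
  few <- new("DisplacementField", points = grid[c(1, 2, 7, 43), ],
             displacements = u[c(1, 2, 7, 43), ],
             status = rep("converged", 4), windowSide = 1.3,
             quality = rep(1, 4))
  expect_error(strainGeers(few), "too few")
})

test_that("grid strain tracks a smooth radial field within 2 %", {
  # fine grid so the least-squares neighbourhood resolves the curvature
  grid <- as.matrix(expand.grid(seq(2, 50, 1), seq(2, 50, 1), seq(2, 10, 1)))
  ax <- c(26, 26)
  dx <- grid[, 1] - ax[1]; dy <- grid[, 2] - ax[2]
  r <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  a0 <- 1.5; lam <- 15
  ur <- a0 * exp(-r / lam)
  u <- cbind(dx * ur / r, dy * ur / r, 0)
  fld <- new("DisplacementField", points = grid, displacements = u,
             status = rep("converged", nrow(grid)), windowSide = 1,
             quality = rep(1, nrow(grid)))
  st <- strainGeers(fld)
  durdr <- -a0 / lam * exp(-r / lam)
  ex <- dx / r; ey <- dy / r
  F11 <- 1 + durdr * ex^2 + ur / r * ey^2
  sel <- st@valid & r > 8 & r < 20 & abs(F11 - 1) > 0.005
  expect_lt(median(abs(st@F[sel, 1, 1] - F11[sel]) / abs(F11[sel] - 1)),
            0.02)
})

test_that("discrete tetrahedral strain is exact on affine data", {
  set.seed(15)
  pts <- matrix(runif(90, 0, 10), 30, 3)
  F0 <- diag(3) + matrix(c(0.012, 0.004, -0.001, 0.002, -0.006, 0.003,
                           0, 0.001, 0.008), 3, 3)
  u <- pts %*% t(F0 - diag(3))
  sb <- strainBagi(pts, u)
  expect_gt(sum(sb@valid), 10)
  err <- max(abs(sweep(sb@F[sb@valid, , , drop = FALSE], c(2, 3), F0)))
  expect_lt(err, 1e-10)
  # single tetrahedron with a prescribed stretch along x
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  ut <- tet %*% diag(c(0.02, 0, 0))
  s1 <- strainBagi(tet, ut)
  expect_equal(s1@F[1, , ], diag(c(1.02, 1, 1)), tolerance = 1e-12)
})

test_that("rigid rotation produces only second-order volumetric strain", {
  set.seed(16)
  pts <- matrix(runif(120, 0, 10), 40, 3)
  th <- pi / 180 # one degree
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  u <- pts %*% t(R - diag(3))
  sb <- strainBagi(pts, u)
  expect_lt(max(abs(sb@epsV[sb@valid])), 2e-4)
})

test_that("grid and tetrahedral strain agree on affine fields", {
  grid <- as.matrix(expand.grid(1:5, 1:5, 1:5)) * 2
  F0 <- diag(3) + matrix(c(0.01, 0, 0.002, 0, -0.004, 0, 0.001, 0, 0.006),
                         3, 3)
  u <- grid %*% t(F0 - diag(3))
  fld <- new("DisplacementField", points = grid, displacements = u,
             status = rep("converged", nrow(grid)), windowSide = 2,
             quality = rep(1, nrow(grid)))
  sg <- strainGeers(fld)
  sb <- strainBagi(grid, u)
  expect_lt(max(abs(sweep(sg@F[sg@valid, , , drop = FALSE], c(2, 3), F0))),
            1e-10)
  expect_lt(max(abs(sweep(sb@F[sb@valid, , , drop = FALSE], c(2, 3), F0))),
            1e-10)
})

test_that("strain invariants match their closed forms", {
  iso <- strainInvariants(1.01 * diag(3))
  expect_equal(iso$epsV, 1.01^3 - 1, tolerance = 1e-12)
  expect_equal(iso$epsQ, 0, tolerance = 1e-12)
  Fs <- diag(3); Fs[1, 3] <- 0.02
  sh <- strainInvariants(Fs)
  expect_equal(sh$epsV, 0, tolerance = 1e-12)
  expect_equal(sh$epsQ, 0.02 / sqrt(2), tolerance = 1e-12)
  idn <- strainInvariants(diag(3))
  expect_equal(c(idn$epsV, idn$epsQ), c(0, 0))
  # von Mises convention differs by sqrt(2/3)
  vm <- strainInvariants(Fs, convention = "vonmises")
  expect_equal(vm$epsQ, sqrt(2 / 3) * 0.02 / sqrt(2), tolerance = 1e-12)
  # non-finite gradients are masked, not propagated
  bad <- array(NA_real_, c(1, 3, 3))
  expect_true(is.na(strainInvariants(bad)$epsV))
})

test_that("engaged volume and strain clouds follow their definitions", {
  n <- 100
  st <- new("StrainField", points = matrix(runif(3 * n), n),
            F = array(rep(diag(3), each = n), c(n, 3, 3)),
            epsV = runif(n, -0.01, 0.01),
            epsQ = c(rep(0.005, 50), rep(0.02, 50)),
            support = rep(26L, n), valid = rep(TRUE, n))
  eng <- engagedVolumeMask(st, 0.01)
  expect_equal(sum(eng$mask), 50)
  expect_equal(eng$fraction, 0.5)
  expect_equal(sum(engagedVolumeMask(st, 0)$mask), 100)
  st0 <- st; st0@epsQ <- rep(0, n)
  expect_equal(sum(engagedVolumeMask(st0, 0.01)$mask), 0)
  # uniform field: near and far centroids coincide
  stu <- st
  stu@epsV <- rep(0.004, n)
  stu@epsQ <- rep(0.02, n)
  rd <- c(rep(0.5, 40), rep(3, 60))
  cl <- strainClouds(stu, rd, nearMax = 1, farMax = 5)
  cn <- cl$centroids
  expect_equal(cn$mean_eps_v[cn$zone == "near"],
               cn$mean_eps_v[cn$zone == "far"])
  # all points inside the root: empty clouds
  expect_message(cl0 <- strainClouds(stu, rep(0, n)), "empty")
  expect_equal(nrow(cl0$cloud), 0L)
})
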