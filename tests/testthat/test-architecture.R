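# Skeletonization, branch hierarchy and architecture metrics.

test_that("a straight cylinder yields one branch of the right length and size", {
  cyl <- array(FALSE, c(21, 21, 100))
  disc <- outer((1:21) - 11, (1:21) - 11, function(x, y) x^2 + y^2 <= 25)
  for (k in 1:100) cyl[, , k] <- disc
  g <- skeletonGraph(cyl, 80)
  br <- branches(g)
  expect_equal(nrow(br), 1L)
  # centre-to-centre axis length is 99 voxels; within 2 % of 100
  expect_gt(sum(br$length_mm) / 0.08, 97)
  expect_lt(sum(br$length_mm) / 0.08, 101)
  # cross-section size (2 x radius estimate) is 10 px +/- 1
  cs <- 2 * mean(skeletonNodes(g)$radius_um) / 80
  expect_gt(cs, 9)
  expect_lt(cs, 11)
})

test_that("radius estimates on cylinders of 3-10 px have sub-half-pixel bias", {
  for (r in c(3, 5, 8, 10)) {
    n <- 2 * r + 7
    c0 <- (n + 1) / 2
    disc <- outer(seq_len(n) - c0, seq_len(n) - c0,
                  function(x, y) x^2 + y^2 <= r^2)
    cyl <- array(FALSE, c(n, n, 40))
    for (k in 1:40) cyl[, , k] <- disc
    g <- skeletonGraph(cyl, 1)
    nd <- skeletonNodes(g)
    mid <- nd[nd$z > 10 & nd$z < 30, ]
    expect_lt(abs(mean(mid$radius_um) - r), 0.5)
  }
})

test_that("a Y-shaped tube has one junction and three endpoints", {
  yt <- array(FALSE, c(40, 21, 60))
  for (k in 1:30) yt[18:22, 9:13, k] <- TRUE
  for (k in 31:60) {
    o <- (k - 30) %/% 2
    yt[18:22 - o, 9:13, k] <- TRUE
    yt[18:22 + o, 9:13, k] <- TRUE
  }
  g <- skeletonGraph(yt, 80)
  expect_equal(nrow(branches(g)), 3L)
  deg <- igraph::degree(igraph::graph_from_edgelist(g@edges,
                                                    directed = FALSE))
  expect_equal(sum(deg == 1L), 3L)
  expect_equal(sum(deg >= 3L), 1L)
})

test_that("branch lengths partition the skeleton without double counting", {
  sc <- fineScene()
  seg <- segmentScene(sc)
  g <- skeletonGraph(seg$root$mask, voxelSize(sc@volume))
  br <- branches(g)
  # every edge is walked exactly once by the branch decomposition
  paths <- attr(br, "paths")
  nEdgesWalked <- sum(vapply(paths, length, 0L) - 1L)
  expect_equal(nEdgesWalked, nrow(g@edges))
  # branch lengths sum to the raw polyline total up to the centreline
  # smoothing (which only removes staircase overshoot)
  elen <- sqrt(rowSums((as.matrix(g@nodes[g@edges[, 1], c("x", "y", "z")]) -
                        as.matrix(g@nodes[g@edges[, 2], c("x", "y", "z")]))^2))
  raw <- sum(elen) * voxelSize(sc@volume) * 1e-3
  expect_lte(sum(br$length_mm), raw)
  expect_gte(sum(br$length_mm), 0.9 * raw)
})

test_that("the skeleton of a segmented synthetic root matches the truth", {
  sc <- fineScene()
  seg <- segmentScene(sc)
  g <- skeletonGraph(seg$root$mask, voxelSize(sc@volume))
  g <- labelHierarchy(g, sc@seedVoxel)
  # mean distance from recovered skeleton nodes to the true centreline
  truth <- as.matrix(skeletonNodes(sc@skeleton)[, c("x", "y", "z")])
  nd <- as.matrix(skeletonNodes(g)[, c("x", "y", "z")])
  dmin <- vapply(seq_len(nrow(nd)), function(i)
    sqrt(min(colSums((t(truth) - nd[i, ])^2))), 0)
  expect_lte(mean(dmin), 1.5)
  br <- branches(g)
  expect_equal(sum(br$order == 1L), 1L)
  # recovered total length within 40 % of the truth: the seed-kernel zone
  # and thin tapered lateral tips near the resolution limit are lost
  expect_lt(abs(sum(br$length_mm) - sum(branches(sc@skeleton)$length_mm)) /
              sum(branches(sc@skeleton)$length_mm), 0.4)
})

test_that("hierarchy labelling on the exact synthetic skeleton is exact", {
  cfg <- sceneConfig(nLaterals = 3L, rngSeed = 12L)
  rt <- generateRootSystem(cfg)
  g <- skeletonGraph(rt$mask, cfg@voxelSize)
  g <- labelHierarchy(g, rt$seedVoxel)
  br <- branches(g)
  expect_equal(sum(br$order == 1L), 1L)
  expect_equal(sum(br$order == 2L), 3L)
})

test_that("skeleton length is stable under 90-degree rotation", {
  sc <- fineScene()
  seg <- segmentScene(sc)
  mask <- seg$root$mask
  g1 <- skeletonGraph(mask, 80)
  mask2 <- aperm(mask, c(3, 2, 1)) # swap x and z
  g2 <- skeletonGraph(mask2, 80)
  l1 <- sum(branches(g1)$length_mm)
  l2 <- sum(branches(g2)$length_mm)
  expect_lt(abs(l1 - l2) / l1, 0.03)
})

test_that("architecture metrics follow their definitions", {
  # RLD: 0.589 m of root in the 5 cm x 10 cm cell volume is 3000 m/m^3
  br <- data.frame(branch = 1L, order = 1L, parent = 0L,
                   length_mm = 589, n_nodes = 2L)
  nodes <- data.frame(node = 1:2, x = c(1, 1), y = c(1, 1), z = c(1, 50),
                      radius_um = c(300, 300), branch = 1L)
  g <- new("RootSkeletonGraph", nodes = nodes,
           edges = matrix(c(1L, 2L), 1), branches = br, voxelSize = 80)
  m <- architectureMetrics(g, soilVolume_mm3 = pi * 25^2 * 100)
  expect_equal(m$rld_m_per_m3, 3000, tolerance = 0.001)
  expect_equal(m$n_laterals, 0L)
  # elongation rate: unchanged primary between days gives 0
  m2 <- architectureMetrics(g, 1000, priorPrimaryLengths_mm = c(500, 589))
  expect_equal(m2$elongation_rate_mm_day, 0)
  # RLD of an unbranched synthetic root within 3 % of the ground truth
  # (the length of the imaged root phase; tissue inside the seed kernel is
  # not imaged)
  sc0 <- cachedScene(33L, nLaterals = 0L)
  mask0 <- phaseLabels(sc0@phases) == 3L
  gg <- labelHierarchy(skeletonGraph(mask0, voxelSize(sc0@volume)),
                       sc0@seedVoxel)
  d <- dim(mask0)
  soil <- prod(d[1:2]) * (d[3] - sc0@surfaceZ) * (voxelSize(sc0@volume) * 1e-3)^3
  m3 <- architectureMetrics(gg, soil, sc0@surfaceZ)
  tr <- skeletonNodes(sc0@skeleton)
  iv <- cbind(pmin(pmax(round(tr$x), 1), d[1]), pmin(pmax(round(tr$y), 1), d[2]),
              pmin(pmax(round(tr$z), 1), d[3]))
  inPhase <- mask0[iv]
  steps <- sqrt(rowSums(diff(as.matrix(tr[, c("x", "y", "z")]))^2))
  truth_mm <- sum(steps[inPhase[-1] & inPhase[-length(inPhase)]]) *
    voxelSize(sc0@volume) * 1e-3
  truthRld <- (truth_mm * 1e-3) / (soil * 1e-9)
  expect_lt(abs(m3$rld_m_per_m3 - truthRld) / truthRld, 0.03)
  # branched roots lose junction and tapered-tip length: within 15 %
  sc <- fineScene()
  ggb <- labelHierarchy(skeletonGraph(phaseLabels(sc@phases) == 3L,
                                      voxelSize(sc@volume)), sc@seedVoxel)
  db <- dim(phaseLabels(sc@phases))
  soilb <- prod(db[1:2]) * (db[3] - sc@surfaceZ) * (voxelSize(sc@volume) * 1e-3)^3
  m4 <- architectureMetrics(ggb, soilb, sc@surfaceZ)
  truthRldB <- (sum(branches(sc@skeleton)$length_mm) * 1e-3) / (soilb * 1e-9)
  expect_lt(abs(m4$rld_m_per_m3 - truthRldB) / truthRldB, 0.15)
})
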