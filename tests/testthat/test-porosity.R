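# Porosity profiles, porosity-change extent, degree of saturation.

test_that("vertical profiles are flat on homogeneous media and exact on trivial ones", {
  ph <- constructedPhases(c(60, 60, 80), porosity = 0.475, seed = 1,
                          pattern = "lowdisc")
  vp <- verticalPorosityProfile(ph, 0.8)
  expect_true(all(abs(vp@table$porosity - 0.475) <= 0.01))
  # all-pore volume: every slab is 1
  allpore <- fourPhaseVolume(array(0L, c(10, 10, 20)), 80)
  vp1 <- verticalPorosityProfile(allpore, 0.4)
  expect_true(all(vp1@table$porosity == 1))
})

test_that("a linear porosity gradient is recovered", {
  dims <- c(50, 50, 100)
  set.seed(2)
  p_of_z <- seq(0.35, 0.55, length.out = dims[3])
  lab <- array(0L, dims)
  for (k in seq_len(dims[3]))
    lab[, , k] <- ifelse(runif(prod(dims[1:2])) < p_of_z[k], 0L, 2L)
  ph <- fourPhaseVolume(lab, 80)
  vp <- verticalPorosityProfile(ph, 0.8)
  tb <- vp@table
  fit <- coef(lm(porosity ~ mid_mm, data = tb))
  trueSlope <- (0.55 - 0.35) / (dims[3] * 0.08)
  expect_lt(abs(fit[2] - trueSlope) / trueSlope, 0.05)
})

test_that("shell porosity is flat around a root in a homogeneous medium", {
  ph <- constructedPhases(c(64, 64, 64), porosity = 0.475,
                          rootRadius_vox = 4, seed = 3, pattern = "lowdisc")
  sp <- shellPorosityProfile(ph, spec = shellSpec(169, maxDistance_mm = 2))
  tb <- sp@table[!sp@table$low_support, ]
  expect_true(all(abs(tb$porosity - 0.475) <= 0.01))
})

test_that("shell binning equals a brute-force nearest-distance oracle", {
  ph <- constructedPhases(c(40, 40, 40), porosity = 0.45,
                          rootRadius_vox = 3, seed = 4)
  lab <- phaseLabels(ph)
  root <- lab == 3L
  sp <- shellPorosityProfile(ph, root, shellSpec(160, maxDistance_mm = 1.2))
  # oracle: per-voxel distance to the nearest root voxel, binned directly
  rvox <- which(root, arr.ind = TRUE)
  d <- dim(lab)
  th <- 160 / 80 # shell thickness in voxels
  nb <- nrow(sp@table)
  cnt <- integer(nb); pore <- integer(nb)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (root[i, j, k]) next
    dist <- sqrt(min((rvox[, 1] - i)^2 + (rvox[, 2] - j)^2 + (rvox[, 3] - k)^2))
    if (dist <= 0) next
    b <- ceiling(dist / th)
    if (b > nb) next
    cnt[b] <- cnt[b] + 1L
    if (lab[i, j, k] %in% c(0L, 1L)) pore[b] <- pore[b] + 1L
  }
  expect_equal(sp@table$voxel_count, cnt)
  expect_equal(sp@table$porosity[cnt > 0], (pore / pmax(cnt, 1))[cnt > 0],
               tolerance = 1e-12)
})

test_that("shell porosities aggregate to the porosity of the union region", {
  ph <- constructedPhases(c(48, 48, 48), porosity = 0.5,
                          rootRadius_vox = 3, seed = 5)
  sp <- shellPorosityProfile(ph, spec = shellSpec(240, maxDistance_mm = 1.5))
  tb <- sp@table[sp@table$voxel_count > 0, ]
  agg <- sum(tb$porosity * tb$voxel_count) / sum(tb$voxel_count)
  lab <- phaseLabels(ph)
  dist <- distanceTransform(lab == 3L) * 80
  inr <- lab != 3L & dist > 0 & dist <= ceiling(1500 / 240) * 240 &
    ceiling(dist / 240) <= nrow(sp@table)
  expect_equal(agg, sum(lab[inr] %in% c(0L, 1L)) / sum(inr), tolerance = 1e-12)
})

test_that("profiles are invariant to axis permutation", {
  ph <- constructedPhases(c(40, 40, 40), porosity = 0.45,
                          rootRadius_vox = 3, seed = 6)
  lab2 <- aperm(phaseLabels(ph), c(2, 1, 3))
  ph2 <- fourPhaseVolume(lab2, 80)
  s1 <- shellPorosityProfile(ph, spec = shellSpec(160, 1.2))
  s2 <- shellPorosityProfile(ph2, spec = shellSpec(160, 1.2))
  expect_equal(s1@table$porosity, s2@table$porosity, tolerance = 1e-12)
})

test_that("a constructed +0.05 porosity zone is recovered to one shell", {
  dims <- c(100, 100, 60)
  base <- constructedPhases(dims, porosity = 0.45, rootRadius_vox = 4,
                            seed = 7)
  lab <- phaseLabels(base)
  root <- lab == 3L
  dist_um <- distanceTransform(root) * 80
  # raise porosity by +0.05 within 2.5 mm of the root surface
  set.seed(8)
  zone <- which(dist_um > 0 & dist_um <= 2500 & lab == 2L)
  nzone <- sum(dist_um > 0 & dist_um <= 2500 & lab != 3L)
  lab2 <- lab
  lab2[sample(zone, round(0.05 * nzone))] <- 0L
  # mild compaction outside the zone (looser-sand pattern): the dilated
  # zone then ends with a sharp crossing of the initial bulk porosity
  outs <- which(dist_um > 2500 & lab == 0L)
  nout <- sum(dist_um > 2500 & lab != 3L)
  lab2[sample(outs, round(0.01 * nout))] <- 2L
  mod <- fourPhaseVolume(lab2, 80)
  spec <- shellSpec(169, maxDistance_mm = 3.5)
  p0 <- shellPorosityProfile(base, root, spec)
  p1 <- shellPorosityProfile(mod, root, spec)
  dp <- deltaPorosityProfile(p1, p0, bulkPorosity0 = 0.45)
  tb <- dp$table
  elevated <- which(tb$delta_n > 0.025)
  expect_lte(max(tb$upper_mm[elevated]), 2.5 + 0.169)
  expect_gte(max(tb$upper_mm[elevated]), 2.5 - 0.169)
  expect_true(all(diff(elevated) == 1)) # contiguous from the root
  expect_lte(abs(dp$extent_mm - 2.5), 0.169 + 1e-9)
  # identical profiles: delta 0 everywhere, compaction-only off
  d0 <- deltaPorosityProfile(p0, p0, bulkPorosity0 = 0.45)
  expect_true(all(abs(d0$table$delta_n) < 1e-12, na.rm = TRUE))
  # a profile below bulk everywhere: extent 0 with the compaction flag
  dlow <- deltaPorosityProfile(p0, p0, bulkPorosity0 = 0.99)
  expect_equal(dlow$extent_mm, 0)
  expect_true(dlow$compaction_only)
})

test_that("degree-of-saturation maps follow the water distribution", {
  dims <- c(30, 30, 40)
  lab <- array(0L, dims)
  lab[, , 21:40] <- 1L # saturated below a table at z = 20
  ph <- fourPhaseVolume(lab, 80)
  sr <- degreeOfSaturationMap(ph, window_mm = 0.4)
  expect_true(all(sr[, , 1:15] == 0))
  expect_true(all(sr[, , 26:40] == 1))
  # transition at the table depth within one window
  prof <- apply(sr, 3, mean)
  cross <- which(prof > 0.5)[1]
  expect_lte(abs(cross - 20.5), 5.5)
  # fully dry / fully saturated trivial cases
  dry <- fourPhaseVolume(array(0L, c(10, 10, 10)), 80)
  expect_true(all(degreeOfSaturationMap(dry, 0.4) == 0))
  # windows without pore voxels are undefined
  solid <- fourPhaseVolume(array(2L, c(10, 10, 10)), 80)
  expect_true(all(is.na(degreeOfSaturationMap(solid, 0.4))))
})
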