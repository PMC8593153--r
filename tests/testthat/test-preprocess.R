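# Histogram peaks, contrast stretch, downscaling, bilateral denoising.

test_that("histogram peaks of a two-Gaussian mixture are recovered", {
  set.seed(2)
  x <- c(rnorm(4e5, 80, 10), rnorm(6e5, 180, 10))
  vol <- greyVolume(array(x, c(100, 100, 100)), 40)
  pk <- findHistogramPeaks(vol, 2)
  expect_lt(abs(pk@peaks[1] - 80), 2)
  expect_lt(abs(pk@peaks[2] - 180), 2)
  expect_error(findHistogramPeaks(greyVolume(array(7, c(5, 5, 5)), 40), 2),
               "degenerate|maxima")
})

test_that("rendered scene peaks sit at the configured grey means", {
  sc <- cachedScene(10L, psfSigma = 0, noiseSigma = 3)
  pk <- findHistogramPeaks(sc@volume, 2)
  gm <- sc@config@greyMeans
  expect_lt(abs(pk@peaks[1] - gm[["air"]]), 2)
  expect_lt(abs(pk@peaks[2] - gm[["sand"]]), 2)
})

test_that("contrast stretch maps anchor peaks onto the reference exactly", {
  vol <- greyVolume(array(runif(8000, 40, 210), c(20, 20, 20)), 40)
  # identity when peaks equal the reference
  same <- contrastStretch(vol, peakSet(c(50, 200)), peakSet(c(50, 200)))
  expect_equal(as.vector(same@data), as.vector(vol@data), tolerance = 1e-12)
  # two-anchor affine: (50, 200) -> (60, 220) sends 125 to 140
  st <- contrastStretch(vol, peakSet(c(50, 200)), peakSet(c(60, 220)))
  expect_equal(as.vector(st@data), 60 + (as.vector(vol@data) - 50) * 160 / 150,
               tolerance = 1e-12)
  expect_error(contrastStretch(vol, peakSet(c(100, 100 + 1e-16)),
                               peakSet(c(60, 220))),
               "coincident|increasing")
})

test_that("stretched volumes re-detect peaks at the reference positions", {
  set.seed(3)
  x <- c(rnorm(3e5, 70, 8), rnorm(3e5, 160, 8))
  vol <- greyVolume(array(x, c(100, 100, 60)), 40)
  pk <- findHistogramPeaks(vol, 2)
  ref <- peakSet(c(90, 200), reference = TRUE)
  st <- contrastStretch(vol, pk, ref)
  pk2 <- findHistogramPeaks(st, 2)
  expect_lt(max(abs(pk2@peaks - ref@peaks)), 1.01)
  # idempotence: once peaks match the reference, the map is the identity
  st2 <- contrastStretch(st, pk2, ref)
  expect_lt(max(abs(st2@data - st@data)), 1.5)
})

test_that("downscale is exact block averaging with the right bookkeeping", {
  a <- array(0:7, c(2, 2, 2))
  v <- greyVolume(a, 40)
  d2 <- downscale(v, 2)
  expect_equal(as.vector(d2@data), 3.5)
  expect_equal(voxelSize(d2), 80)
  # voxel count drops by the cube of the factor; grey sum is conserved
  big <- greyVolume(array(runif(40 * 40 * 40), c(40, 40, 40)), 40)
  d <- downscale(big, 2)
  expect_equal(length(d@data), length(big@data) / 8)
  expect_equal(sum(d@data) * 8, sum(big@data), tolerance = 1e-9)
  expect_identical(downscale(big, 1), big)
  # non-divisible dimensions are cropped
  odd <- greyVolume(array(1, c(5, 4, 4)), 40)
  expect_message(dd <- downscale(odd, 2), "crop")
  expect_equal(dim(dd@data), c(2L, 2L, 2L))
})

test_that("bilateral filtering smooths flat regions but keeps edges", {
  set.seed(4)
  a <- array(100, c(30, 30, 30))
  a[16:30, , ] <- 200
  noisy <- a + array(rnorm(27000, 0, 5), dim(a))
  vol <- greyVolume(noisy, 80)
  out <- denoiseBilateral(vol, 2, sigmaRange = 15)
  # constant regions: noise reduced
  expect_lt(sd(out@data[3:12, 3:28, 3:28]), sd(noisy[3:12, 3:28, 3:28]) / 2)
  # output stays within the input range
  expect_gte(min(out@data), min(noisy))
  expect_lte(max(out@data), max(noisy))
  # edge location (half-maximum crossing) moves by less than a voxel
  prof <- apply(out@data[, 3:28, 3:28], 1, mean)
  cross <- which(prof > 150)[1]
  expect_lte(abs(cross - 16), 1)
  # a constant volume passes through unchanged
  cv <- greyVolume(array(42, c(10, 10, 10)), 80)
  expect_equal(denoiseBilateral(cv, 2, sigmaRange = 10)@data, cv@data,
               tolerance = 1e-12)
})

test_that("preprocessing commutes with spatial axis permutation", {
  set.seed(5)
  a <- array(runif(24 * 24 * 24, 0, 255), c(24, 24, 24))
  vol <- greyVolume(a, 40)
  pa <- aperm(a, c(3, 1, 2))
  pvol <- greyVolume(pa, 40)
  expect_equal(aperm(downscale(vol, 2)@data, c(3, 1, 2)),
               downscale(pvol, 2)@data, tolerance = 1e-12)
  expect_equal(aperm(denoiseBilateral(vol, 1.5, sigmaRange = 20)@data,
                     c(3, 1, 2)),
               denoiseBilateral(pvol, 1.5, sigmaRange = 20)@data,
               tolerance = 1e-9)
})
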