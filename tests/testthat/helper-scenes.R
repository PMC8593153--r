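# Shared fixtures: synthetic scenes are expensive (~10 s each), so they are
# built once per session and cached by their configuration.

.sceneCache <- new.env(parent = emptyenv())

cachedScene <- function(seed, ...) {
  key <- paste0("s", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  if (!exists(key, .sceneCache)) {
    assign(key, synthScene(sceneConfig(rngSeed = seed, ...)), .sceneCache)
  }
  get(key, .sceneCache)
}

# default fine-sand study scene used across module tests
fineScene <- function() cachedScene(101L)

# full segmentation chain against ground-truth calibration targets, as the
# pipeline would run it (denoise, volume-calibrated sand, variance-filter
# root, volume-calibrated water)
segmentScene <- function(sc, rv = 2L) {
  key <- paste0("seg_", substr(digestVolume(sc@volume), 1, 12), "_rv", rv)
  if (exists(key, .sceneCache)) return(get(key, .sceneCache))
  gt <- phaseLabels(sc@phases)
  vol <- denoiseBilateral(sc@volume, 2)
  vv <- (vol@voxelSize * 1e-3)^3
  cal <- calibrateThresholdByVolume(vol, sum(gt == 2L) * vv, side = "above")
  sand <- segmentSand(vol, cal$threshold)
  rs <- suppressWarnings(segmentRoot(vol, varianceSegParams(rv), sand))
  wa <- segmentWaterAir(vol, sand, rs$mask,
                        waterVolume_mm3 = sum(gt == 1L) * vv)
  phases <- assembleFourPhase(sand, rs$mask, wa$water, wa$air, vol@voxelSize)
  res <- list(volume = vol, sand = sand, root = rs, water = wa,
              phases = phases, gt = gt, vv = vv)
  assign(key, res, .sceneCache)
  res
}

digestVolume <- function(vol) {
  paste0(dim(vol@data)[1], "x", dim(vol@data)[3], "_",
         format(sum(vol@data), digits = 12))
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# brute-force windowed population variance (triple loop oracle)
bruteVariance <- function(a, rv) {
  d <- dim(a)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    w <- a[max(1, i - rv):min(d[1], i + rv),
           max(1, j - rv):min(d[2], j + rv),
           max(1, k - rv):min(d[3], k + rv)]
    out[i, j, k] <- mean(w^2) - mean(w)^2
  }
  out
}

# random four-phase volume at a given porosity with a vertical cylindrical
# root of the given radius (voxels) through the centre. pattern "lowdisc"
# uses an incommensurate-rotation (low-discrepancy) pore assignment whose
# porosity is near-exact over any sizeable region; "iid" is Bernoulli.
constructedPhases <- function(dims, porosity, rootRadius_vox = 0,
                              voxel = 80, seed = 1, pattern = "iid") {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  lab <- if (pattern == "lowdisc") {
    g <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                     k = seq_len(dims[3]))
    u <- (g$i * 0.7548776662 + g$j * 0.5698402910 + g$k * 0.3287194241 +
            seed * 0.1234567) %% 1
    array(ifelse(u < porosity, 0L, 2L), dims)
  } else {
    withr_seed(array(ifelse(runif(prod(dims)) < porosity, 0L, 2L), dims))
  }
  if (rootRadius_vox > 0) {
    cx <- dims[1] / 2 + 0.5; cy <- dims[2] / 2 + 0.5
    r2 <- outer((seq_len(dims[1]) - cx)^2, (seq_len(dims[2]) - cy)^2, "+")
    tube <- r2 <= rootRadius_vox^2
    for (k in seq_len(dims[3])) {
      sl <- lab[, , k]
      sl[tube] <- 3L
      lab[, , k] <- sl
    }
  }
  fourPhaseVolume(lab, voxel)
}
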