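# Four-phase segmentation: air / water / sand / root.
#
# Sand is the densest (brightest) phase and is thresholded with a grey
# value calibrated so the segmented volume matches the known mass of dry
# sand. Roots have greys close to pore water, so they are segmented with a
# 3D variance filter: homogeneous regions (root interior, background air,
# large pores) score low variance, granular sand scores high; ranking the
# low-variance connected components by volume identifies background and
# root, and the eroded root edge is recovered by dilation.

#' Physical sand volume from dry mass
#'
#' @param mass_g dry sand mass in grams.
#' @param grainDensity grain density in g/cm^3 (default 2.65, silica).
#' @return Solid volume in mm^3.
#' @export
sandVolumeFromMass <- function(mass_g, grainDensity = 2.65) {
  stopifnot(mass_g > 0, grainDensity > 0)
  mass_g / grainDensity * 1000
}

#' Calibrate a grey threshold against a known physical volume
#'
#' Returns the threshold for which the segmented volume (voxels with grey
#' above/below the threshold within the domain) best matches the target
#' physical volume. The segmented volume is monotone in the threshold, so
#' the optimum is read directly off the sorted grey values.
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param targetVolume_mm3 physical volume to match (e.g. from
#'   \code{\link{sandVolumeFromMass}} or the poured water volume).
#' @param side "above" (phase brighter than threshold) or "below".
#' @param domainMask optional logical array restricting the calibration.
#' @return list with \code{threshold}, \code{achieved_mm3},
#'   \code{residual_mm3} and \code{target_voxels}.
#' @export
calibrateThresholdByVolume <- function(volume, targetVolume_mm3,
                                       side = c("above", "below"),
                                       domainMask = NULL) {
  side <- match.arg(side)
  stopifnot(is(volume, "GreyVolume"))
  g <- volume@data
  if (!is.null(domainMask)) g <- g[domainMask]
  vv <- (volume@voxelSize * 1e-3)^3
  domain_mm3 <- length(g) * vv
  if (targetVolume_mm3 <= 0 || targetVolume_mm3 >= domain_mm3)
    stop(sprintf("target volume %.3f mm^3 outside the domain volume (%.3f mm^3)",
                 targetVolume_mm3, domain_mm3))
  k <- round(targetVolume_mm3 / vv)
  k <- min(max(k, 1L), length(g))
  gs <- sort(g, decreasing = (side == "above"))
  thr <- gs[k] # including ties, at least k voxels pass
  nseg <- if (side == "above") sum(g >= thr) else sum(g <= thr)
  achieved <- nseg * vv
  residual <- achieved - targetVolume_mm3
  # one histogram-bin worth of volume at unit grey resolution
  binvol <- length(g) / max(diff(range(g)), 1) * vv
  if (abs(residual) > binvol)
    warning(sprintf("volume calibration residual %.3f mm^3 exceeds one bin (%.3f mm^3); best threshold %.2f",
                    residual, binvol, thr))
  list(threshold = thr, achieved_mm3 = achieved, residual_mm3 = residual,
       target_voxels = k)
}

#' Threshold the sand phase
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param threshold calibrated grey threshold.
#' @return Logical sand mask (grey >= threshold).
#' @export
segmentSand <- function(volume, threshold) {
  stopifnot(is(volume, "GreyVolume"))
  volume@data >= threshold
}

#' Label individual grains by marker-based watershed
#'
#' Computes the Euclidean distance transform inside the sand mask, smooths
#' it, takes its regional maxima as grain markers and floods the negated
#' distance map. Intended for coarse sand where a grain spans tens of
#' voxels. Labels smaller than \code{minGrainVolume} are merged into the
#' neighbouring label with the largest shared boundary.
#'
#' @param sandMask logical 3D array.
#' @param minGrainVolume minimum label size in voxels.
#' @param smoothSigma Gaussian sd (voxels) applied to the distance map
#'   before maxima detection.
#' @return Integer label array (0 background) with attribute \code{n}.
#' @export
labelGrainsWatershed <- function(sandMask, minGrainVolume = 27L,
                                 smoothSigma = 1) {
  stopifnot(is.logical(sandMask), length(dim(sandMask)) == 3L)
  d <- dim(sandMask)
  if (!any(sandMask)) {
    lab <- array(0L, d)
    attr(lab, "n") <- 0L
    return(lab)
  }
  edt <- distanceTransform(!sandMask)
  sm <- gaussianBlur3d(edt, smoothSigma)
  # regional maxima: value equals the 26-neighbourhood running maximum
  mx <- sm
  for (ax in 1:3) {
    dd <- dim(mx)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(mx, perm)
    dm <- dim(m)
    m2 <- pmax(m,
               m[c(1, seq_len(dm[1] - 1)), , , drop = FALSE],
               m[c(seq_len(dm[1] - 1) + 1, dm[1]), , , drop = FALSE])
    mx <- aperm(m2, order(perm))
  }
  markers <- sandMask & (sm >= mx - 1e-9) & edt >= 1
  mlab <- labelComponents(markers, 26L) # a plateau is a single marker
  lab <- cpp_watershed3d(as.vector(-edt), as.vector(mlab),
                         as.vector(sandMask), as.integer(d), 26L)
  dim(lab) <- d
  # merge undersized labels into their dominant neighbour
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  small <- which(sizes > 0 & sizes < minGrainVolume)
  if (length(small)) {
    for (s in small) {
      vox <- which(lab == s)
      if (!length(vox)) next
      nb <- integer(0)
      for (off in c(1, -1, d[1], -d[1], d[1] * d[2], -d[1] * d[2])) {
        q <- vox + off
        q <- q[q >= 1 & q <= length(lab)]
        nb <- c(nb, lab[q])
      }
      nb <- nb[nb > 0L & nb != s]
      if (length(nb)) lab[vox] <- as.integer(names(which.max(table(nb))))
    }
    # compact label ids
    u <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], u)
  }
  attr(lab, "n") <- length(unique(lab[lab > 0L]))
  lab
}

#' 3D variance filter
#'
#' Replaces each voxel by the population variance of the greys in the
#' cubic window of half-width \code{rv} centred on it (windows are clipped
#' at the image edges). Phase interfaces score high, homogeneous interiors
#' score low.
#'
#' @param volume a \linkS4class{GreyVolume} or 3D array.
#' @param rv window half-width in voxels (>= 1).
#' @return Numeric 3D array of variances.
#' @export
varianceFilter <- function(volume, rv) {
  a <- if (is(volume, "GreyVolume")) volume@data else volume
  stopifnot(length(dim(a)) == 3L, rv >= 1)
  rv <- as.integer(rv)
  cnt <- boxSum3d(array(1, dim(a)), rv)
  s1 <- boxSum3d(a, rv)
  s2 <- boxSum3d(a * a, rv)
  pmax(s2 / cnt - (s1 / cnt)^2, 0)
}

#' Parameters of the variance-filter root segmentation
#'
#' The dilation count recovering the root edge is half the variance window
#' radius (rounded down, minimum 1): \code{rv = 4} for fine sand gives 2
#' dilations, \code{rv = 2} for coarse sand gives 1.
#'
#' @param rv variance window half-width in voxels.
#' @param dilationCount edge-recovery dilations; default
#'   \code{max(1, floor(rv / 2))}.
#' @param varianceThreshold numeric threshold on the variance map, or NA
#'   for automatic selection: 0.45 x the median variance of the sand
#'   matrix (Otsu on the square-root variance when no sand mask is
#'   available). The matrix-median rule is exactly scale-equivariant under
#'   affine grey transforms.
#' @return list of class parameters used by \code{\link{segmentRoot}}.
#' @export
varianceSegParams <- function(rv, dilationCount = NULL,
                              varianceThreshold = NA_real_) {
  stopifnot(rv >= 1)
  if (is.null(dilationCount)) dilationCount <- max(1L, as.integer(rv) %/% 2L)
  stopifnot(dilationCount >= 1)
  list(rv = as.integer(rv), dilationCount = as.integer(dilationCount),
       varianceThreshold = varianceThreshold)
}

#' Segment the root body with the 3D variance filter
#'
#' Pipeline: variance filter, keep low-variance voxels, label connected
#' components, rank by volume. The largest component is the image
#' background (air above the sand surface), the second largest is the root
#' body, the remainder are connected pores; with \code{background = FALSE}
#' the largest component is taken as the root. Ties in volume are broken
#' towards the component with the lower mean variance (more homogeneous).
#' The root component is then dilated \code{dilationCount} times (Euclidean
#' ball) to recover the edge excluded by the filter, without ever
#' overwriting sand.
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param params from \code{\link{varianceSegParams}}.
#' @param sandMask logical sand mask (the dilation cannot enter it).
#' @param background TRUE when the field of view includes air above the
#'   sand surface.
#' @param greyFloor final verification against the greyscale image: mask
#'   voxels darker than this grey (air-like) are returned to the pore
#'   class. "auto" splits the non-sand greys with Otsu (air versus
#'   water/root); NULL disables the check.
#' @return list with \code{mask} (logical root mask), \code{components}
#'   (volume-ranked component table), \code{threshold} (variance threshold
#'   used).
#' @export
segmentRoot <- function(volume, params, sandMask, background = TRUE,
                        greyFloor = "auto") {
  stopifnot(is(volume, "GreyVolume"))
  d <- dim(volume@data)
  vmap <- varianceFilter(volume, params$rv)
  thr <- params$varianceThreshold
  if (is.na(thr)) {
    # auto threshold: halfway (x0.45) to the granular matrix's median
    # variance -- scale-equivariant under affine grey transforms, sits
    # between homogeneous interiors and the grain/pore texture
    thr <- if (any(sandMask)) 0.45 * median(vmap[sandMask]) else
      otsuThreshold(sqrt(vmap))^2
  }
  low <- vmap <= thr
  lab <- labelComponents(low, 26L)
  sizes <- attr(lab, "sizes")
  if (length(sizes) < (if (background) 2L else 1L))
    stop("no root candidate: fewer than two low-variance components")
  meanVar <- vapply(seq_along(sizes), function(i) mean(vmap[lab == i]), 0)
  ord <- order(sizes, -meanVar, decreasing = TRUE) # ties: lower mean variance later? see below
  # rank by volume; on exact volume ties prefer lower mean variance as root
  ord <- ord[order(sizes[ord], decreasing = TRUE)]
  comp <- data.frame(id = ord, voxels = sizes[ord], mean_variance = meanVar[ord])
  comp$class <- "connected_pore"
  if (background) {
    comp$class[1] <- "background"
    rootRow <- 2L
    if (nrow(comp) >= 3L && comp$voxels[2] == comp$voxels[3])
      rootRow <- if (comp$mean_variance[2] <= comp$mean_variance[3]) 2L else 3L
  } else {
    rootRow <- 1L
    if (nrow(comp) >= 2L && comp$voxels[1] == comp$voxels[2])
      rootRow <- if (comp$mean_variance[1] <= comp$mean_variance[2]) 1L else 2L
  }
  comp$class[rootRow] <- "root"
  core <- lab == comp$id[rootRow]
  # border contact warning: possible background/root swap
  bbox <- apply(which(core, arr.ind = TRUE), 2, range)
  touch <- sum(bbox[1, ] == 1L) + sum(bbox[2, ] == d)
  if (touch > 3L)
    warning("root component touches the image border on most of its bounding box; possible background/root swap")
  mask <- dilateMask(core, params$dilationCount) & !sandMask
  if (!is.null(greyFloor)) {
    if (identical(greyFloor, "auto"))
      greyFloor <- otsuThreshold(volume@data[!sandMask])
    mask <- mask & volume@data >= greyFloor
    # regrow the sub-voxel shell blurred by the point spread: a closing
    # step constrained to plausible (non-sand, root-grey) voxels
    mask <- erodeMask(dilateMask(mask, 1.8), 1) & !sandMask &
      volume@data >= greyFloor
    # the regrowth may touch nearby pore pockets: keep only the part of
    # the mask connected to the variance-filter core
    lab2 <- labelComponents(mask, 26L)
    keep <- unique(lab2[core & mask])
    keep <- keep[keep > 0L]
    if (length(keep)) mask <- mask & array(lab2 %in% keep, dim(mask))
  }
  # resolution check: a cross-section below 4 voxels is at the method's
  # detectability limit
  cs <- if (any(mask)) 2 * sqrt(max(distanceTransform(!mask, squared = TRUE)[mask])) else 0
  list(mask = mask, components = comp, threshold = thr,
       crossSection_vox = cs, detectable = cs >= 4)
}

#' Segment water and air in the remaining pore space
#'
#' Thresholds the voxels assigned to neither sand nor root (water is
#' brighter than air). The threshold is calibrated once against the poured
#' water volume on the Day-0 image and then reused on later days by
#' passing \code{threshold} directly.
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param sandMask,rootMask logical arrays.
#' @param waterVolume_mm3 poured water volume for Day-0 calibration (0 for
#'   a dry specimen); ignored when \code{threshold} is given.
#' @param threshold previously calibrated grey threshold.
#' @return list with \code{water}, \code{air} (logical masks),
#'   \code{threshold}, \code{achieved_mm3}.
#' @export
segmentWaterAir <- function(volume, sandMask, rootMask,
                            waterVolume_mm3 = NULL, threshold = NULL) {
  stopifnot(is(volume, "GreyVolume"))
  remain <- !(sandMask | rootMask)
  vv <- (volume@voxelSize * 1e-3)^3
  if (is.null(threshold)) {
    if (is.null(waterVolume_mm3))
      stop("either waterVolume_mm3 or threshold must be given")
    pore_mm3 <- sum(remain) * vv
    if (waterVolume_mm3 > pore_mm3)
      stop(sprintf("water target %.2f mm^3 exceeds the pore volume %.2f mm^3",
                   waterVolume_mm3, pore_mm3))
    if (waterVolume_mm3 <= 0) {
      threshold <- Inf
    } else {
      cal <- calibrateThresholdByVolume(volume, waterVolume_mm3,
                                        side = "above", domainMask = remain)
      threshold <- cal$threshold
    }
  }
  water <- remain & volume@data >= threshold
  air <- remain & !water
  list(water = water, air = air, threshold = threshold,
       achieved_mm3 = sum(water) * vv)
}

#' Assemble the four-phase volume
#'
#' Resolves mask overlaps with the precedence sand > root > water > air and
#' checks that every voxel receives exactly one label.
#'
#' @param sand,root,water,air logical masks covering the domain.
#' @param voxelSize voxel size in micrometres.
#' @return A \linkS4class{FourPhaseVolume}.
#' @export
assembleFourPhase <- function(sand, root, water, air, voxelSize) {
  d <- dim(sand)
  stopifnot(identical(d, dim(root)), identical(d, dim(water)),
            identical(d, dim(air)))
  covered <- sand | root | water | air
  if (!all(covered))
    stop(sprintf("%d voxels left unlabelled by the four masks", sum(!covered)))
  labels <- array(0L, d)
  labels[water] <- 1L
  labels[root] <- 3L
  labels[sand] <- 2L
  labels[!(sand | root | water)] <- 0L
  # precedence: sand wins over root wins over water wins over air
  labels[root & !sand] <- 3L
  labels[water & !sand & !root] <- 1L
  fourPhaseVolume(labels, voxelSize)
}
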