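# Soil kinematics: displacement fields by local DIC (fine sand) or grain
# tracking (coarse sand), transformation gradients F, and the strain
# invariants eps_v = det(F) - 1 (dilation positive) and eps_q (norm of the
# deviatoric part of the small-strain tensor).

#' Local (window) digital image correlation
#'
#' Splits the volume into a structured grid of cubic correlation windows
#' and measures, for each, the translation that best registers reference
#' and deformed images: integer-voxel normalised cross-correlation search
#' followed by iterative sub-voxel refinement (trilinear-interpolated
#' least squares). Featureless and low-correlation windows are flagged
#' \code{poor_correlation}, windows too close to the border
#' \code{out_of_bounds}.
#'
#' @param ref,def \linkS4class{GreyVolume}s of identical shape and voxel
#'   size.
#' @param windowSide_mm window side length (default 1.3 mm).
#' @param gridSpacing_mm grid spacing; defaults to the window side
#'   (non-overlapping windows).
#' @param searchRadius_vox integer search range in voxels (expected
#'   displacements must stay below a quarter window).
#' @param nccFloor minimum acceptable correlation peak (default 0.6).
#' @param minVariance grey-variance floor below which a window is
#'   considered featureless.
#' @param presmoothSigma Gaussian sd (voxels) applied to both volumes
#'   before correlation; smooths the interpolated residual landscape so
#'   the sub-voxel iteration converges on sharp granular texture. 0
#'   disables.
#' @return A \linkS4class{DisplacementField} (positions/displacements in
#'   mm).
#' @export
localDIC <- function(ref, def, windowSide_mm = 1.3, gridSpacing_mm = NULL,
                     searchRadius_vox = 4L, nccFloor = 0.6,
                     minVariance = 1, presmoothSigma = 1) {
  stopifnot(is(ref, "GreyVolume"), is(def, "GreyVolume"),
            identical(dim(ref@data), dim(def@data)),
            isTRUE(all.equal(ref@voxelSize, def@voxelSize)))
  v <- ref@voxelSize
  d <- dim(ref@data)
  refData <- ref@data
  defData <- def@data
  if (presmoothSigma > 0) {
    refData <- gaussianBlur3d(refData, presmoothSigma)
    defData <- gaussianBlur3d(defData, presmoothSigma)
  }
  w <- max(3L, round(windowSide_mm * 1000 / v))
  half <- w %/% 2L
  if (is.null(gridSpacing_mm)) gridSpacing_mm <- windowSide_mm
  sp <- max(1L, round(gridSpacing_mm * 1000 / v))
  cx <- seq(half + 1L, d[1] - half, by = sp)
  cy <- seq(half + 1L, d[2] - half, by = sp)
  cz <- seq(half + 1L, d[3] - half, by = sp)
  centers <- as.matrix(expand.grid(cx, cy, cz))
  res <- cpp_dic(as.vector(refData), as.vector(defData), as.integer(d),
                 centers - 1L, as.integer(half),
                 as.integer(searchRadius_vox), minVariance, nccFloor,
                 30L, 1e-3)
  status <- c("converged", "out_of_bounds", "poor_correlation")[res[, 5] + 1]
  pts <- (centers - 0.5) * v * 1e-3
  disp <- res[, 1:3, drop = FALSE] * v * 1e-3
  disp[status != "converged", ] <- NA_real_
  fld <- new("DisplacementField", points = pts, displacements = disp,
             status = status, windowSide = w * v * 1e-3,
             quality = ifelse(status == "converged", res[, 4], NA_real_))
  attr(fld@points, "grid_dims") <- c(length(cx), length(cy), length(cz))
  fld
}

#' Track labelled grains between two days
#'
#' Matches grains by nearest centre of mass within \code{maxDisp_mm},
#' gated on the volume ratio, resolving conflicts by greedy global
#' assignment on distance. Unmatched reference grains are flagged.
#'
#' @param labelsRef,labelsDef integer grain-label arrays (from
#'   \code{\link{labelGrainsWatershed}}).
#' @param voxelSize voxel size in micrometres.
#' @param maxDisp_mm search radius for the centroid match.
#' @param volumeRatio acceptable def/ref grain volume ratio range.
#' @return A \linkS4class{DisplacementField}; points are reference grain
#'   centroids (mm).
#' @export
trackParticles <- function(labelsRef, labelsDef, voxelSize, maxDisp_mm = 1,
                           volumeRatio = c(0.8, 1.25)) {
  cen <- function(lab) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    ijk <- arrayInd(idx, dim(lab))
    n <- tabulate(l)
    keep <- n > 0
    cbind(rowsum(ijk[, 1], l) / n[keep], rowsum(ijk[, 2], l) / n[keep],
          rowsum(ijk[, 3], l) / n[keep], n[keep])
  }
  cr <- cen(labelsRef)
  cd <- cen(labelsDef)
  v <- voxelSize * 1e-3 # mm per voxel
  maxd <- maxDisp_mm / v
  nr <- nrow(cr)
  pairs <- NULL
  for (i in seq_len(nr)) {
    dd <- sqrt((cd[, 1] - cr[i, 1])^2 + (cd[, 2] - cr[i, 2])^2 +
               (cd[, 3] - cr[i, 3])^2)
    ratio <- cd[, 4] / cr[i, 4]
    ok <- which(dd <= maxd & ratio >= volumeRatio[1] & ratio <= volumeRatio[2])
    if (length(ok))
      pairs <- rbind(pairs, cbind(i, ok, dd[ok]))
  }
  match_def <- rep(NA_integer_, nr)
  if (!is.null(pairs)) {
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    usedR <- logical(nr)
    usedD <- logical(nrow(cd))
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      if (!usedR[i] && !usedD[j]) {
        match_def[i] <- j
        usedR[i] <- TRUE
        usedD[j] <- TRUE
      }
    }
  }
  disp <- matrix(NA_real_, nr, 3)
  ok <- !is.na(match_def)
  disp[ok, ] <- (cd[match_def[ok], 1:3, drop = FALSE] -
                 cr[ok, 1:3, drop = FALSE]) * v
  new("DisplacementField", points = cr[, 1:3, drop = FALSE] * v - v / 2,
      displacements = disp,
      status = ifelse(ok, "converged", "unmatched"),
      windowSide = NA_real_, quality = rep(NA_real_, nr))
}

# neighbour lists within a radius, via spatial bucketing
.neighbourLists <- function(points, radius) {
  n <- nrow(points)
  key <- floor(points / radius)
  kstr <- paste(key[, 1], key[, 2], key[, 3])
  buckets <- split(seq_len(n), kstr)
  env <- list2env(buckets, hash = TRUE)
  lapply(seq_len(n), function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(key[i, 1] + dx, key[i, 2] + dy, key[i, 3] + dz)
      b <- env[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    dd <- sqrt(rowSums((points[cand, , drop = FALSE] -
                        matrix(points[i, ], length(cand), 3, byrow = TRUE))^2))
    cand[dd <= radius]
  })
}

#' Strain field from a displacement grid (least-squares gradient)
#'
#' Per-point transformation gradient F = I + du/dX, where du/dX is the
#' uniform-weight least-squares fit of relative displacements against
#' relative positions over the point's neighbourhood (by default the 26
#' surrounding grid points). Points with fewer than 4 usable neighbours or
#' a (near-)coplanar neighbourhood are masked.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param radius_mm neighbourhood radius; defaults to 1.75 x the median
#'   nearest-neighbour spacing (captures the 26 grid neighbours).
#' @param convention deviatoric norm convention, see
#'   \code{\link{strainInvariants}}.
#' @return A \linkS4class{StrainField} at the converged points.
#' @export
strainGeers <- function(field, radius_mm = NULL,
                        convention = c("frobenius", "vonmises")) {
  convention <- match.arg(convention)
  ok <- field@status == "converged"
  pts <- field@points[ok, , drop = FALSE]
  dsp <- field@displacements[ok, , drop = FALSE]
  n <- nrow(pts)
  if (n < 5L) stop("too few converged points for strain estimation")
  if (is.null(radius_mm)) {
    samp <- pts[seq(1, n, length.out = min(n, 200L)), , drop = FALSE]
    dd <- as.matrix(dist(samp))
    diag(dd) <- Inf
    radius_mm <- 1.75 * stats::median(apply(dd, 1, min))
  }
  nb <- .neighbourLists(pts, radius_mm)
  FF <- array(NA_real_, c(n, 3, 3))
  support <- integer(n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    j <- nb[[i]]
    support[i] <- length(j)
    if (length(j) < 4L) next
    A <- sweep(pts[j, , drop = FALSE], 2, pts[i, ])
    B <- sweep(dsp[j, , drop = FALSE], 2, dsp[i, ])
    M <- crossprod(A)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (ev[3] < 1e-10 * ev[1]) next # coplanar neighbourhood
    G <- t(solve(M, crossprod(A, B))) # G = du/dX
    FF[i, , ] <- diag(3) + G
    valid[i] <- TRUE
  }
  inv <- strainInvariants(FF, convention = convention)
  new("StrainField", points = pts, F = FF, epsV = inv$epsV, epsQ = inv$epsQ,
      support = support, valid = valid)
}

#' Discrete strain on a Delaunay tetrahedralisation
#'
#' Builds a Delaunay tetrahedral mesh over the measurement points (grain
#' centres) and computes the per-tetrahedron uniform displacement gradient
#' of the linear interpolant of the nodal displacements — the equivalent
#' continuum strain of a particle assembly. Degenerate tetrahedra are
#' dropped; slivers are flagged as invalid.
#'
#' @param points n x 3 matrix of positions (mm).
#' @param displacements n x 3 matrix of displacements (mm).
#' @param qualityFloor minimum shape quality (tet volume over the cube of
#'   its RMS edge, relative to a regular tetrahedron) below which a
#'   tetrahedron is flagged.
#' @param convention deviatoric norm convention.
#' @return A \linkS4class{StrainField} at tetrahedron centroids.
#' @export
strainBagi <- function(points, displacements, qualityFloor = 0.02,
                       convention = c("frobenius", "vonmises")) {
  convention <- match.arg(convention)
  stopifnot(nrow(points) >= 4L, identical(dim(points), dim(displacements)))
  keep <- rowSums(is.finite(points)) == 3 & rowSums(is.finite(displacements)) == 3
  pts <- points[keep, , drop = FALSE]
  dsp <- displacements[keep, , drop = FALSE]
  # tiny deterministic jitter breaks cospherical ties (grid data); the
  # strain below is still computed from the true coordinates
  span <- max(apply(pts, 2, function(x) diff(range(x))), 1e-9)
  jit <- withSeed(1903L, matrix(runif(length(pts), -1, 1), nrow(pts)) *
                          1e-6 * span)
  tets <- cpp_delaunay3d(pts + jit)
  if (nrow(tets) == 0L) stop("degenerate point set: no tetrahedra")
  m <- nrow(tets)
  FF <- array(NA_real_, c(m, 3, 3))
  cent <- matrix(NA_real_, m, 3)
  epsOK <- logical(m)
  quality <- numeric(m)
  for (t in seq_len(m)) {
    vtx <- tets[t, ]
    X <- t(pts[vtx[2:4], , drop = FALSE]) - pts[vtx[1], ]
    U <- t(dsp[vtx[2:4], , drop = FALSE]) - dsp[vtx[1], ]
    vol <- det(X) / 6
    edges <- cbind(X, X[, 2] - X[, 1], X[, 3] - X[, 1], X[, 3] - X[, 2])
    rmsE <- sqrt(mean(colSums(edges^2)))
    quality[t] <- abs(vol) / (rmsE^3 / (6 * sqrt(2))) # 1 for a regular tet
    if (abs(vol) < 1e-12 * rmsE^3) next
    G <- U %*% solve(X)
    FF[t, , ] <- diag(3) + G
    cent[t, ] <- colMeans(pts[vtx, , drop = FALSE])
    epsOK[t] <- quality[t] >= qualityFloor
  }
  inv <- strainInvariants(FF, convention = convention)
  fld <- new("StrainField", points = cent, F = FF, epsV = inv$epsV,
             epsQ = inv$epsQ, support = rep(4L, m), valid = epsOK)
  attr(fld@points, "tets") <- tets
  fld
}

#' Strain invariants of a transformation gradient
#'
#' Volumetric strain \code{eps_v = det(F) - 1} (dilation positive) and
#' deviatoric strain \code{eps_q}: the Frobenius ("Euclidean") norm of the
#' traceless part of the small-strain tensor \code{sym(F) - I}, or its
#' von Mises scaling \code{sqrt(2/3) ||dev||} when requested.
#'
#' @param F a 3 x 3 matrix or an n x 3 x 3 array.
#' @param convention "frobenius" (default) or "vonmises".
#' @return list with \code{epsV} and \code{epsQ} (scalars or vectors);
#'   non-finite gradients yield NA.
#' @export
strainInvariants <- function(F, convention = c("frobenius", "vonmises")) {
  convention <- match.arg(convention)
  if (is.matrix(F)) {
    FF <- array(F, c(1, 3, 3))
    one <- TRUE
  } else {
    FF <- F
    one <- FALSE
  }
  n <- dim(FF)[1]
  epsV <- rep(NA_real_, n)
  epsQ <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Fi <- FF[i, , ]
    if (any(!is.finite(Fi))) next
    epsV[i] <- det(Fi) - 1
    eps <- (Fi + t(Fi)) / 2 - diag(3)
    dev <- eps - sum(diag(eps)) / 3 * diag(3)
    q <- sqrt(sum(dev^2))
    if (convention == "vonmises") q <- sqrt(2 / 3) * q
    epsQ[i] <- q
  }
  if (one) list(epsV = epsV[1], epsQ = epsQ[1]) else
    list(epsV = epsV, epsQ = epsQ)
}

#' Engaged-volume mask
#'
#' The volume of soil engaged by root growth: measurement points where the
#' deviatoric strain exceeds the threshold (1\% by default, which filters
#' shear-strain noise).
#'
#' @param strain a \linkS4class{StrainField}.
#' @param threshold deviatoric strain threshold (fraction).
#' @return list with \code{mask} (logical over the strain points) and
#'   \code{fraction} (engaged share of valid points).
#' @export
engagedVolumeMask <- function(strain, threshold = 0.01) {
  stopifnot(is(strain, "StrainField"))
  mask <- strain@valid & !is.na(strain@epsQ) & strain@epsQ > threshold
  list(mask = mask, fraction = sum(mask) / max(sum(strain@valid), 1L))
}

#' Distance from strain points to the root, in window units
#'
#' Marks the correlation windows containing root voxels and returns, for
#' each query point, the Euclidean distance (in window side lengths) to
#' the nearest root-containing window. Points inside root windows get 0.
#'
#' @param rootMask logical root mask on the voxel grid.
#' @param voxelSize voxel size (um).
#' @param windowSide_mm correlation window side (mm).
#' @param points_mm n x 3 positions to evaluate (mm).
#' @return Numeric vector of distances in window units.
#' @export
rootDistanceByWindow <- function(rootMask, voxelSize, windowSide_mm,
                                 points_mm) {
  d <- dim(rootMask)
  w <- max(1L, round(windowSide_mm * 1000 / voxelSize))
  gd <- pmax(1L, ceiling(d / w))
  occ <- array(FALSE, gd)
  idx <- which(rootMask, arr.ind = TRUE)
  if (nrow(idx)) {
    gi <- (idx - 1L) %/% w + 1L
    occ[gi] <- TRUE
  }
  if (!any(occ)) return(rep(Inf, nrow(points_mm)))
  dt <- distanceTransform(occ) # in window units
  pv <- points_mm / (voxelSize * 1e-3) + 0.5 # voxel coordinates
  pw <- floor((pv - 0.5) / w) + 1L
  pw[, 1] <- pmin(pmax(pw[, 1], 1L), gd[1])
  pw[, 2] <- pmin(pmax(pw[, 2], 1L), gd[2])
  pw[, 3] <- pmin(pmax(pw[, 3], 1L), gd[3])
  dt[as.matrix(pw)]
}

#' Near/far strain clouds around the root
#'
#' Partitions the engaged measurement points into an immediate-vicinity
#' zone (within \code{nearMax} window widths of a root-containing window)
#' and a further-neighbourhood zone (up to \code{farMax}), excluding
#' points inside root windows, and returns the (eps_q, eps_v) cloud per
#' zone plus the eps_v centroid per eps_q bin — the orange-line summary of
#' the volumetric response at a given shear level.
#'
#' @param strain a \linkS4class{StrainField}.
#' @param rootDist per-point distance to the root in window units (from
#'   \code{\link{rootDistanceByWindow}}).
#' @param nearMax,farMax zone radii in window units (defaults 1 and 5).
#' @param qBinWidth eps_q bin width for the centroid trend.
#' @param engagedThreshold only points with eps_q above this enter the
#'   clouds (NULL: all valid points).
#' @return list with \code{cloud} (data.frame zone, eps_q, eps_v) and
#'   \code{centroids} (data.frame zone, q_mid, mean_eps_v, n).
#' @export
strainClouds <- function(strain, rootDist, nearMax = 1, farMax = 5,
                         qBinWidth = 0.005, engagedThreshold = 0.01) {
  stopifnot(is(strain, "StrainField"),
            length(rootDist) == length(strain@epsQ))
  use <- strain@valid & rootDist > 0 & rootDist <= farMax
  if (!is.null(engagedThreshold)) use <- use & strain@epsQ > engagedThreshold
  zone <- ifelse(rootDist <= nearMax, "near", "far")
  cloud <- data.frame(zone = zone[use], eps_q = strain@epsQ[use],
                      eps_v = strain@epsV[use])
  if (nrow(cloud) == 0L) {
    message("strain clouds are empty (no engaged points in range)")
    return(list(cloud = cloud,
                centroids = data.frame(zone = character(0), q_mid = numeric(0),
                                       mean_eps_v = numeric(0), n = integer(0))))
  }
  cloud$q_bin <- floor(cloud$eps_q / qBinWidth)
  agg <- aggregate(eps_v ~ zone + q_bin, data = cloud, FUN = mean)
  cnt <- aggregate(eps_v ~ zone + q_bin, data = cloud, FUN = length)
  centroids <- data.frame(zone = agg$zone,
                          q_mid = (agg$q_bin + 0.5) * qBinWidth,
                          mean_eps_v = agg$eps_v, n = cnt$eps_v)
  list(cloud = cloud[, c("zone", "eps_q", "eps_v")], centroids = centroids)
}
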