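# Porosity profiles and saturation maps.
#
# Porosity is the ratio of pore (air + water) voxels to soil voxels, where
# soil excludes the root body. Coaxial shell profiles bin the soil voxels
# by Euclidean distance from the root surface, optionally restricted to
# voxels whose nearest root voxel belongs to a selected branch.

.zArray <- function(d) array(rep(seq_len(d[3]), each = prod(d[1:2])), d)

#' Vertical (depth-wise) porosity profile
#'
#' Porosity of horizontal slabs of the given thickness, excluding slabs at
#' and above the seed depth (the seed disturbs the pluviated packing).
#'
#' @param phases a \linkS4class{FourPhaseVolume}.
#' @param slabThickness_mm slab thickness in mm (>= 1 voxel).
#' @param excludeAboveZ voxel index; slabs ending above this depth are
#'   dropped (use the seed position; 0 keeps everything below the surface).
#' @param surfaceZ first sand slice (voxel index); air above the surface is
#'   never counted as pore space.
#' @param dayIndex day stamp for the profile.
#' @return A \linkS4class{PorosityProfile} of kind "vertical".
#' @export
verticalPorosityProfile <- function(phases, slabThickness_mm = 0.4,
                                    excludeAboveZ = 0L, surfaceZ = 0L,
                                    dayIndex = 0L) {
  stopifnot(is(phases, "FourPhaseVolume"))
  lab <- phases@labels
  d <- dim(lab)
  v <- phases@voxelSize
  slab_vox <- max(1L, round(slabThickness_mm * 1000 / v))
  z0 <- max(as.integer(excludeAboveZ), as.integer(surfaceZ))
  rows <- list()
  k0 <- z0 + 1L
  while (k0 <= d[3]) {
    k1 <- min(k0 + slab_vox - 1L, d[3])
    sl <- lab[, , k0:k1]
    soil <- sl != 3L # root voxels are not soil
    ntot <- sum(soil)
    if (ntot > 0) {
      pore <- sum(sl == 0L | sl == 1L)
      rows[[length(rows) + 1L]] <-
        data.frame(lower_mm = (k0 - 1L) * v * 1e-3, upper_mm = k1 * v * 1e-3,
                   mid_mm = (k0 + k1 - 1L) / 2 * v * 1e-3,
                   porosity = pore / ntot, voxel_count = ntot,
                   low_support = ntot < 100L)
    }
    k0 <- k1 + 1L
  }
  if (!length(rows)) stop("no slabs below the exclusion depth")
  new("PorosityProfile", table = do.call(rbind, rows), kind = "vertical",
      dayIndex = as.integer(dayIndex))
}

#' Shell specification for root-distance porosity profiles
#'
#' @param shellThickness_um shell thickness; D50/2 by convention.
#' @param maxDistance_mm outermost shell distance (default 16).
#' @param branch branch id to centre the shells on (NA: whole root).
#' @param wallMargin_mm voxels closer than this to the lateral image border
#'   are excluded.
#' @return list of shell parameters.
#' @export
shellSpec <- function(shellThickness_um, maxDistance_mm = 16,
                      branch = NA_integer_, wallMargin_mm = 0) {
  stopifnot(shellThickness_um > 0,
            maxDistance_mm * 1000 > shellThickness_um)
  list(shellThickness_um = shellThickness_um, maxDistance_mm = maxDistance_mm,
       branch = branch, wallMargin_mm = wallMargin_mm)
}

#' Porosity in coaxial shells around the root surface
#'
#' Soil voxels are binned into concentric iso-distance shells of the
#' Euclidean distance transform of the root surface (a "hollow volume"
#' coaxial with the root axis, generalising to curved axes). With a branch
#' selector, only voxels whose nearest root voxel belongs to that branch
#' are counted. Root voxels are excluded from numerator and denominator;
#' shells with fewer than 100 voxels are flagged as low support.
#'
#' @param phases a \linkS4class{FourPhaseVolume}.
#' @param rootMask logical root mask (phase 3 of \code{phases} if NULL).
#' @param spec from \code{\link{shellSpec}}.
#' @param skeleton optional \linkS4class{RootSkeletonGraph} used to assign
#'   root voxels to branches when \code{spec$branch} is set.
#' @param surfaceZ first sand slice; voxels above it are excluded.
#' @param dayIndex day stamp.
#' @return A \linkS4class{PorosityProfile} of kind "shell".
#' @export
shellPorosityProfile <- function(phases, rootMask = NULL, spec,
                                 skeleton = NULL, surfaceZ = 0L,
                                 dayIndex = 0L) {
  stopifnot(is(phases, "FourPhaseVolume"))
  lab <- phases@labels
  d <- dim(lab)
  v <- phases@voxelSize
  if (is.null(rootMask)) rootMask <- lab == 3L
  if (!any(rootMask)) stop("empty root mask")
  distAll <- distanceTransform(rootMask) * v # um from the root surface
  inc <- !rootMask
  if (surfaceZ > 0) inc <- inc & .zArray(d) > surfaceZ
  if (spec$wallMargin_mm > 0) {
    m <- round(spec$wallMargin_mm * 1000 / v)
    border <- array(TRUE, d)
    if (d[1] > 2 * m && d[2] > 2 * m)
      border[(m + 1):(d[1] - m), (m + 1):(d[2] - m), ] <- FALSE
    inc <- inc & !border
  }
  dist_um <- distAll
  if (!is.na(spec$branch)) {
    if (is.null(skeleton))
      stop("a skeleton is required to select shells around a single branch")
    nd <- skeleton@nodes
    sel <- nd$branch == spec$branch
    if (!any(sel)) stop(sprintf("branch %d not present", spec$branch))
    toVox <- function(rows) {
      m <- array(FALSE, d)
      iv <- cbind(pmin(pmax(round(nd$x[rows]), 1), d[1]),
                  pmin(pmax(round(nd$y[rows]), 1), d[2]),
                  pmin(pmax(round(nd$z[rows]), 1), d[3]))
      m[iv] <- TRUE
      m
    }
    # split the root phase into branch territories by nearest skeleton node
    selOwn <- .nearestIs(toVox(sel), toVox(!sel), d)
    rootSel <- rootMask & selOwn
    rootOth <- rootMask & !selOwn
    dSel <- distanceTransform(rootSel)
    dOth <- if (any(rootOth)) distanceTransform(rootOth) else array(Inf, d)
    inc <- inc & (dSel < dOth) # ownership by nearest branch
    dist_um <- dSel * v
  }
  th <- spec$shellThickness_um
  nshell <- floor(spec$maxDistance_mm * 1000 / th)
  bin <- pmin(ceiling(dist_um / th), nshell + 1L)
  use <- inc & bin <= nshell & dist_um > 0
  b <- bin[use]
  pore <- (lab == 0L | lab == 1L)[use]
  cnt <- tabulate(b, nbins = nshell)
  por <- tabulate(b[pore], nbins = nshell) / pmax(cnt, 1L)
  tab <- data.frame(lower_mm = (seq_len(nshell) - 1) * th * 1e-3,
                    upper_mm = seq_len(nshell) * th * 1e-3,
                    mid_mm = (seq_len(nshell) - 0.5) * th * 1e-3,
                    porosity = ifelse(cnt > 0, por, NA_real_),
                    voxel_count = cnt, low_support = cnt < 100L)
  new("PorosityProfile", table = tab, kind = "shell",
      dayIndex = as.integer(dayIndex))
}

# voxels of mask A that are nearer to A's skeleton than to B's
.nearestIs <- function(skelA, skelB, d) {
  if (!any(skelB)) return(array(TRUE, d))
  dA <- cpp_edt_sq(as.vector(skelA), as.integer(d))
  dB <- cpp_edt_sq(as.vector(skelB), as.integer(d))
  out <- dA <= dB
  dim(out) <- d
  out
}

#' Porosity change profile and dilated-zone extent
#'
#' Computes the per-shell porosity change between two days and the extent
#' of the dilated zone: the distance up to which the day-i porosity stays
#' above the initial bulk porosity (first crossing; the dilated zone is
#' contiguous from the root surface).
#'
#' @param profile_i shell \linkS4class{PorosityProfile} at day i.
#' @param profile_0 matching profile at day 0.
#' @param bulkPorosity0 initial bulk porosity of the pack.
#' @return list with \code{table} (adds \code{delta_n}),
#'   \code{extent_mm}, and \code{compaction_only}.
#' @export
deltaPorosityProfile <- function(profile_i, profile_0, bulkPorosity0) {
  t1 <- profile_i@table
  t0 <- profile_0@table
  if (nrow(t1) != nrow(t0) ||
      max(abs(t1$lower_mm - t0$lower_mm)) > 1e-9)
    stop("profiles have mismatching shell bins")
  tab <- t1
  tab$porosity_day0 <- t0$porosity
  tab$delta_n <- t1$porosity - t0$porosity
  ok <- !is.na(t1$porosity)
  above <- t1$porosity > bulkPorosity0
  above[!ok] <- FALSE
  firstBelow <- which(!above)[1]
  extent <- if (is.na(firstBelow)) max(tab$upper_mm) else
    if (firstBelow == 1L) 0 else tab$lower_mm[firstBelow]
  compaction_only <- all(!above[ok])
  list(table = tab, extent_mm = extent, compaction_only = compaction_only)
}

#' Degree-of-saturation map
#'
#' Moving-window proportion of pore space occupied by water:
#' \code{S_r = water / (water + air)} over a cubic window; windows without
#' pore voxels are undefined (NA).
#'
#' @param phases a \linkS4class{FourPhaseVolume}.
#' @param window_mm cubic window side in mm (>= 3 voxels).
#' @return Numeric 3D array of S_r in [0, 1] with NA where undefined.
#' @export
degreeOfSaturationMap <- function(phases, window_mm = 1) {
  stopifnot(is(phases, "FourPhaseVolume"))
  lab <- phases@labels
  v <- phases@voxelSize
  w <- max(3L, round(window_mm * 1000 / v))
  r <- w %/% 2L
  wat <- boxSum3d(array(as.numeric(lab == 1L), dim(lab)), r)
  pore <- boxSum3d(array(as.numeric(lab == 0L | lab == 1L), dim(lab)), r)
  out <- wat / pore
  out[pore == 0] <- NA_real_
  out
}
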