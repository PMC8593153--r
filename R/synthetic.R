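# Synthetic root-in-sand scene generation.
#
# Scenes emulate the study conditions of the imaging campaign: Hostun-like
# sand packs at controlled porosity (fine HN31-like: D50 = 338 um, n in
# 0.39-0.51; coarse HN1.5-2-like: D50 = 1.9 mm, n in 0.28-0.39), a tubular
# branching root carved out of the pore space, partial water saturation,
# and CT-like grey levels (per-phase means, Gaussian PSF, Gaussian noise).
# Every scene carries full ground truth: phase labels, grain centres and
# radii, the exact root skeleton, and (after warpScene) an analytic
# displacement field.

#' SceneConfig: parameters of a synthetic root-in-sand scene
#'
#' Defaults correspond to a desk-scale specimen of fine sand in its looser
#' state: D50 = 338 um, target porosity 0.475 (relative density 28\% within
#' the porosity range 0.39-0.51), 80 um voxels (the working pixel size after
#' factor-2 downscaling of a 40 um acquisition), and a primary root of
#' 300 um radius (0.6 mm cross-section) with three laterals.
#'
#' @slot cellWidth lateral extent of the imaged box (mm).
#' @slot cellHeight vertical extent (mm), z increasing downward.
#' @slot headspace air gap above the sand surface (mm).
#' @slot voxelSize voxel edge (um).
#' @slot d50 median grain diameter (um).
#' @slot grainSizeCV coefficient of variation of the lognormal grain radii.
#' @slot targetPorosity pore fraction of the pack (air + water over total).
#' @slot porosityBounds achievable (loosest, densest) porosity pair.
#' @slot relativeDensity compactness D_R in [0,1]; used to derive
#'   \code{targetPorosity} when that is NA.
#' @slot rootRadius primary-root radius (um).
#' @slot rootTaper tip radius as a fraction of the base radius.
#' @slot tortuosity lateral random-walk scale of the root axis (voxels per
#'   unit step).
#' @slot nLaterals number of order-2 branches.
#' @slot seedDepth seed position below the sand surface (mm).
#' @slot waterTableDepth full saturation below this depth under the sand
#'   surface (mm); Inf = dry.
#' @slot capillaryFringe band above the water table carrying pendular water
#'   at grain contacts (mm).
#' @slot greyMeans named grey values, \code{c(air, water, sand, root)}.
#' @slot noiseSigma additive Gaussian noise sd (grey levels).
#' @slot psfSigma Gaussian point-spread sd (voxels).
#' @slot rngSeed integer seed; identical configs render bit-identical scenes.
#' @export
setClass("SceneConfig", representation(
  cellWidth = "numeric", cellHeight = "numeric", headspace = "numeric",
  voxelSize = "numeric", d50 = "numeric", grainSizeCV = "numeric",
  targetPorosity = "numeric", porosityBounds = "numeric",
  relativeDensity = "numeric", rootRadius = "numeric", rootTaper = "numeric",
  tortuosity = "numeric", nLaterals = "integer", seedDepth = "numeric",
  waterTableDepth = "numeric", capillaryFringe = "numeric",
  greyMeans = "numeric", noiseSigma = "numeric", psfSigma = "numeric",
  rngSeed = "integer"))

setValidity("SceneConfig", function(object) {
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  if (object@cellWidth * 1000 < 10 * object@d50)
    return("cell width must be at least 10 x D50")
  if (object@targetPorosity <= 0 || object@targetPorosity >= 1)
    return("targetPorosity must be in (0, 1)")
  b <- sort(object@porosityBounds)
  if (object@targetPorosity < b[1] - 1e-9 || object@targetPorosity > b[2] + 1e-9)
    return(sprintf("targetPorosity %.3f outside porosity bounds [%.2f, %.2f]",
                   object@targetPorosity, b[1], b[2]))
  gm <- object@greyMeans
  if (!all(c("air", "water", "sand", "root") %in% names(gm)))
    return("greyMeans must name air, water, sand and root")
  if (gm["sand"] <= max(gm["water"], gm["root"]) ||
      min(gm["water"], gm["root"]) <= gm["air"])
    return("greyMeans must satisfy air < (water ~ root) < sand")
  if (object@rootRadius <= 0 || object@nLaterals < 0)
    return("root radius and lateral count must be positive")
  TRUE
})

#' Build a scene configuration
#'
#' Any argument can be overridden; \code{targetPorosity = NA} derives the
#' porosity from \code{relativeDensity} as
#' \code{n_max - D_R * (n_max - n_min)}.
#'
#' @param cellWidth,cellHeight,headspace geometry in mm.
#' @param voxelSize voxel edge in um.
#' @param d50 median grain diameter in um.
#' @param grainSizeCV lognormal CV of grain radii.
#' @param targetPorosity pore fraction; NA to derive from relativeDensity.
#' @param porosityBounds loosest/densest achievable porosities.
#' @param relativeDensity compactness in [0,1].
#' @param rootRadius,rootTaper,tortuosity,nLaterals root geometry.
#' @param seedDepth seed depth below the sand surface (mm).
#' @param waterTableDepth,capillaryFringe water model (mm).
#' @param greyMeans named per-phase grey values.
#' @param noiseSigma,psfSigma imaging model.
#' @param rngSeed integer seed.
#' @return A \linkS4class{SceneConfig}.
#' @export
sceneConfig <- function(cellWidth = 6.4, cellHeight = 9.6, headspace = 1.6,
                        voxelSize = 80, d50 = 338, grainSizeCV = 0.2,
                        targetPorosity = NA_real_,
                        porosityBounds = c(0.39, 0.51),
                        relativeDensity = 0.28,
                        rootRadius = 300, rootTaper = 0.6, tortuosity = 0.1,
                        nLaterals = 3L, seedDepth = 0.8,
                        waterTableDepth = 8, capillaryFringe = Inf,
                        greyMeans = c(air = 30, water = 105, root = 115,
                                      sand = 190),
                        noiseSigma = 5, psfSigma = 0.4, rngSeed = 1L) {
  b <- sort(porosityBounds)
  if (is.na(targetPorosity))
    targetPorosity <- b[2] - relativeDensity * (b[2] - b[1])
  new("SceneConfig", cellWidth = cellWidth, cellHeight = cellHeight,
      headspace = headspace, voxelSize = voxelSize, d50 = d50,
      grainSizeCV = grainSizeCV, targetPorosity = targetPorosity,
      porosityBounds = b, relativeDensity = relativeDensity,
      rootRadius = rootRadius, rootTaper = rootTaper, tortuosity = tortuosity,
      nLaterals = as.integer(nLaterals), seedDepth = seedDepth,
      waterTableDepth = waterTableDepth, capillaryFringe = capillaryFringe,
      greyMeans = greyMeans, noiseSigma = noiseSigma, psfSigma = psfSigma,
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(paste0("SceneConfig: %.1f x %.1f x %.1f mm at %.0f um, D50 %.0f um,",
                     " n* = %.3f, root r = %.0f um, %d laterals, seed %d\n"),
              object@cellWidth, object@cellWidth, object@cellHeight,
              object@voxelSize, object@d50, object@targetPorosity,
              object@rootRadius, object@nLaterals, object@rngSeed))
})

# scene grid dimensions (voxels) and surface depth (voxel index)
.sceneDims <- function(config) {
  v <- config@voxelSize
  c(nx = round(config@cellWidth * 1000 / v),
    ny = round(config@cellWidth * 1000 / v),
    nz = round(config@cellHeight * 1000 / v))
}

.surfaceZ <- function(config) round(config@headspace * 1000 / config@voxelSize)

# voxelise a set of spheres (centres/radii in um) into a logical array
.voxeliseSpheres <- function(centres, radii, dims, voxel) {
  mask <- array(FALSE, dims)
  if (length(radii) == 0) return(mask)
  for (g in seq_along(radii)) {
    cx <- centres[g, 1]; cy <- centres[g, 2]; cz <- centres[g, 3]
    r <- radii[g]
    i0 <- max(1L, floor((cx - r) / voxel + 0.5)); i1 <- min(dims[1], ceiling((cx + r) / voxel + 0.5))
    j0 <- max(1L, floor((cy - r) / voxel + 0.5)); j1 <- min(dims[2], ceiling((cy + r) / voxel + 0.5))
    k0 <- max(1L, floor((cz - r) / voxel + 0.5)); k1 <- min(dims[3], ceiling((cz + r) / voxel + 0.5))
    if (i0 > i1 || j0 > j1 || k0 > k1) next
    xs <- ((i0:i1) - 0.5) * voxel - cx
    ys <- ((j0:j1) - 0.5) * voxel - cy
    zs <- ((k0:k1) - 0.5) * voxel - cz
    d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
    sub <- mask[i0:i1, j0:j1, k0:k1, drop = FALSE] | (d2 <= r^2)
    mask[i0:i1, j0:j1, k0:k1] <- sub
  }
  mask
}

#' Generate a sand grain pack at controlled porosity
#'
#' Places non-overlapping spheres with lognormal radii (median D50/2,
#' configured CV) on a jittered face-centred-cubic lattice and deletes
#' grains at random until the voxelised solid fraction of the sand region
#' matches \code{1 - targetPorosity} to within 0.01. Radii are shrunk
#' pairwise (largest first) so that jittered neighbours never overlap;
#' mechanical deposition is deliberately not simulated.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return list with \code{grains} (data.frame x, y, z, r in um, plus
#'   \code{kept}), \code{solid} (logical array), \code{porosity} (achieved
#'   voxel porosity of the sand region), \code{surfaceZ} (first sand slice).
#' @export
generateGrainPack <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  dims <- .sceneDims(config)
  v <- config@voxelSize
  zsurf <- .surfaceZ(config)
  withSeed(config@rngSeed, {
    d50 <- config@d50
    ann <- 1.05 * d50              # nearest-neighbour lattice distance
    jit <- 0.02 * ann              # jitter amplitude per axis
    a <- ann * sqrt(2)             # cubic FCC lattice constant
    wx <- dims[1] * v; wz <- dims[3] * v
    zs0 <- zsurf * v
    basis <- rbind(c(0, 0, 0), c(.5, .5, 0), c(.5, 0, .5), c(0, .5, .5)) * a
    ii <- seq(0, ceiling(wx / a)); kk <- seq(0, ceiling((wz - zs0) / a))
    grid <- as.matrix(expand.grid(ii * a, ii * a, kk * a + zs0))
    sites <- do.call(rbind, lapply(seq_len(4), function(b)
      sweep(grid, 2, basis[b, ], "+")))
    sites <- sites + matrix(runif(length(sites), -jit, jit), nrow(sites))
    rmin <- d50 / 2 + jit
    keep <- sites[, 1] > -rmin & sites[, 1] < wx + rmin &
            sites[, 2] > -rmin & sites[, 2] < wx + rmin &
            sites[, 3] > zs0 + 0.35 * d50 & sites[, 3] < wz + rmin
    sites <- sites[keep, , drop = FALSE]
    n <- nrow(sites)
    sdlog <- sqrt(log(1 + config@grainSizeCV^2))
    rad <- rlnorm(n, meanlog = log(d50 / 2), sdlog = sdlog)
    # neighbour pairs via spatial buckets
    rc <- 1.25 * ann
    bx <- floor(sites / rc)
    kstr <- paste(bx[, 1], bx[, 2], bx[, 3])
    buckets <- split(seq_len(n), kstr)
    env <- list2env(buckets, hash = TRUE)
    pairs <- vector("list", n)
    for (i in seq_len(n)) {
      cand <- integer(0)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        b <- env[[paste(bx[i, 1] + dx, bx[i, 2] + dy, bx[i, 3] + dz)]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      cand <- cand[cand > i]
      if (!length(cand)) next
      dd2 <- rowSums((sites[cand, , drop = FALSE] -
                      matrix(sites[i, ], length(cand), 3, byrow = TRUE))^2)
      sel <- dd2 < (1.2 * ann)^2
      if (any(sel))
        pairs[[i]] <- cbind(i, cand[sel], sqrt(dd2[sel]))
    }
    P <- do.call(rbind, pairs)
    # resolve overlaps: damped fixed-point of r_i = min(sample_i,
    # min_j (d_ij - r_j)), then a strict pairwise enforcement pass.
    # Preserves the sampled size distribution except where neighbours
    # actually collide.
    if (!is.null(P)) {
      minper <- function(idx, val, init = Inf) {
        o <- order(val, decreasing = TRUE)
        out <- rep(init, n)
        out[idx[o]] <- val[o] # last write wins: the per-index minimum
        out
      }
      idx2 <- c(P[, 1], P[, 2])
      cap <- rad * 1.2 # spheres with local slack may grow a little
      for (it in 1:80) {
        cons <- minper(idx2, c(P[, 3] - rad[P[, 2]], P[, 3] - rad[P[, 1]]))
        rad <- 0.6 * rad + 0.4 * pmin(cap, cons)
      }
      for (it in 1:20) {
        s <- P[, 3] / (rad[P[, 1]] + rad[P[, 2]])
        if (all(s >= 1 - 1e-12)) break
        sv <- pmin(s, 1)
        f <- minper(idx2, c(sv, sv), 1)
        rad <- rad * f
      }
      rad <- rad * (1 - 1e-9)
    }
    # sand analysis region: below the surface
    sandvox <- prod(dims[1:2]) * (dims[3] - zsurf)
    target_solid <- 1 - config@targetPorosity
    measure <- function(keep) {
      m <- .voxeliseSpheres(sites[keep, , drop = FALSE], rad[keep], dims, v)
      sum(m[, , (zsurf + 1):dims[3]]) / sandvox
    }
    keep <- rep(TRUE, n)
    phi_max <- measure(keep)
    if (target_solid > phi_max + 0.01)
      stop(sprintf(paste0("target porosity %.3f is not reachable: achievable ",
                          "porosity range is [%.3f, 1] for this configuration"),
                   config@targetPorosity, 1 - phi_max))
    # random deletion, tuned by secant iterations on the voxelised fraction;
    # deletions are spread out (blue-noise-like) so looseness is homogeneous
    # rather than concentrated in multi-grain cavities
    spreadOrder <- function(ord, minsep) {
      cell <- minsep
      key <- floor(sites / cell)
      env <- new.env(hash = TRUE)
      acc <- integer(n); na <- 0L
      rest <- integer(n); nr <- 0L
      for (i in ord) {
        k0 <- key[i, ]
        okflag <- TRUE
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          b <- env[[paste(k0[1] + dx, k0[2] + dy, k0[3] + dz)]]
          if (!is.null(b) &&
              any(rowSums((sites[b, , drop = FALSE] -
                           matrix(sites[i, ], length(b), 3,
                                  byrow = TRUE))^2) < minsep^2)) {
            okflag <- FALSE
            break
          }
        }
        if (okflag) {
          na <- na + 1L
          acc[na] <- i
          kk <- paste(k0[1], k0[2], k0[3])
          env[[kk]] <- c(env[[kk]], i)
        } else {
          nr <- nr + 1L
          rest[nr] <- i
        }
      }
      c(acc[seq_len(na)], rest[seq_len(nr)])
    }
    if (target_solid < phi_max - 0.001) {
      delOrder <- spreadOrder(sample.int(n), 1.8 * ann)
      frac <- 1 - target_solid / phi_max
      for (it in 1:6) {
        k <- round(frac * n)
        keep <- rep(TRUE, n); keep[delOrder[seq_len(k)]] <- FALSE
        phi <- measure(keep)
        if (abs(phi - target_solid) <= 0.005) break
        frac <- max(0, min(0.95, frac + (phi - target_solid) / phi_max))
      }
    }
    solid <- .voxeliseSpheres(sites[keep, , drop = FALSE], rad[keep], dims, v)
    phi <- sum(solid[, , (zsurf + 1):dims[3]]) / sandvox
    grains <- data.frame(x = sites[, 1], y = sites[, 2], z = sites[, 3],
                         r = rad, kept = keep)
    list(grains = grains, solid = solid, porosity = 1 - phi, surfaceZ = zsurf,
         dims = dims)
  })
}

#' Generate a synthetic root system
#'
#' Grows a tortuous primary axis downward from the seed position, with
#' \code{nLaterals} order-2 branches at random heights, and voxelises the
#' tapering tube. Returns the exact centreline as a
#' \linkS4class{RootSkeletonGraph} with per-node radius.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @return list with \code{skeleton} (\linkS4class{RootSkeletonGraph}),
#'   \code{mask} (logical array), \code{seedVoxel} (x, y, z), and
#'   \code{truncated} (TRUE if any axis was clipped at the cell boundary).
#' @export
generateRootSystem <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  dims <- .sceneDims(config)
  v <- config@voxelSize
  zsurf <- .surfaceZ(config)
  withSeed(config@rngSeed + 101L, {
    r0 <- config@rootRadius / v       # voxels
    seed <- c(dims[1] / 2, dims[2] / 2, zsurf + config@seedDepth * 1000 / v)
    truncated <- FALSE
    margin <- 1.5
    grow_axis <- function(start, dir0, length_plan, r_base, tort) {
      pts <- matrix(start, 1, 3)
      w <- dir0[1:2] / max(dir0[3], 1e-6)
      s <- 0
      while (s < length_plan) {
        w <- w + rnorm(2, 0, tort)
        w <- w * min(1, 0.6 / max(sqrt(sum(w^2)), 1e-9))
        dir <- c(w, 1); dir <- dir / sqrt(sum(dir^2))
        p <- pts[nrow(pts), ] + dir
        if (any(p[1:2] < 1 + margin) || any(p[1:2] > dims[1:2] - margin) ||
            p[3] > dims[3] - margin) {
          truncated <<- TRUE
          break
        }
        pts <- rbind(pts, p)
        s <- s + 1
      }
      pts
    }
    taper_radius <- function(r_base, nsteps) {
      # linear taper from r_base to rootTaper * r_base at the tip
      s <- seq(0, 1, length.out = max(nsteps, 2))
      r_base * (1 - (1 - config@rootTaper) * s)
    }
    L_plan <- dims[3] - margin - seed[3]
    prim <- grow_axis(seed, c(0, 0, 1), L_plan, r0, config@tortuosity)
    rprim <- taper_radius(r0, nrow(prim))
    nodes <- data.frame(x = prim[, 1], y = prim[, 2], z = prim[, 3],
                        radius_um = rprim * v, branch = 1L)
    edges <- if (nrow(prim) > 1) cbind(seq_len(nrow(prim) - 1), 2:nrow(prim)) else
      matrix(integer(0), 0, 2)
    br <- data.frame(branch = 1L, order = 1L, parent = 0L,
                     length_mm = (nrow(prim) - 1) * v * 1e-3,
                     n_nodes = nrow(prim))
    nL <- config@nLaterals
    if (nL > 0) {
      rng <- seq(max(2, round(0.12 * nrow(prim))), round(0.7 * nrow(prim)))
      att <- sort(sample(rng, nL, replace = nL > length(rng)))
      for (tt in 1:20) { # spread the attachment heights
        if (nL < 2 || all(diff(att) >= 6)) break
        att <- sort(sample(rng, nL, replace = nL > length(rng)))
      }
      prevLats <- list()
      for (b in seq_len(nL)) {
        a <- att[b]
        lat <- NULL
        for (try in 1:12) {
          az <- runif(1, 0, 2 * pi)
          pol <- runif(1, 50, 70) * pi / 180   # angle from vertical
          dir0 <- c(sin(pol) * cos(az), sin(pol) * sin(az), cos(pol))
          Llat <- 0.35 * nrow(prim) * runif(1, 0.7, 1.3)
          # laterals run straighter than the primary so they leave its
          # tube cleanly instead of hugging it
          cand <- grow_axis(prim[a, ], dir0, Llat, 0.7 * r0,
                            config@tortuosity * 0.5)
          if (nrow(cand) < 3) next
          # keep laterals clear of each other and of the primary (beyond
          # their attachment zone): crossing tubes merge in the mask
          sep <- 2 * 0.7 * r0 + 2
          nAtt <- min(ceiling(3 * r0) + 2L, nrow(cand) - 1L)
          free <- cand[-seq_len(nAtt), , drop = FALSE]
          if (!nrow(free)) next
          dPrim <- min(sqrt(pmax(outer(rowSums(free^2), rowSums(prim^2), "+") -
                                   2 * free %*% t(prim), 0)))
          dLats <- if (length(prevLats)) min(vapply(prevLats, function(p)
            min(sqrt(pmax(outer(rowSums(free^2), rowSums(p^2), "+") -
                            2 * free %*% t(p), 0))), 0)) else Inf
          if (dPrim > 0.7 * r0 + r0 + 1 && dLats > sep) {
            lat <- cand
            break
          }
        }
        if (is.null(lat)) next
        prevLats[[length(prevLats) + 1L]] <- lat
        rlat <- taper_radius(0.7 * r0, nrow(lat))
        i0 <- nrow(nodes)
        lat_nodes <- data.frame(x = lat[-1, 1], y = lat[-1, 2], z = lat[-1, 3],
                                radius_um = rlat[-1] * v, branch = b + 1L)
        nodes <- rbind(nodes, lat_nodes)
        idx <- c(a, i0 + seq_len(nrow(lat) - 1))
        edges <- rbind(edges, cbind(idx[-length(idx)], idx[-1]))
        br <- rbind(br, data.frame(branch = b + 1L, order = 2L, parent = 1L,
                                   length_mm = sum(sqrt(rowSums(diff(lat)^2))) * v * 1e-3,
                                   n_nodes = nrow(lat) - 1))
      }
    }
    nodes <- cbind(node = seq_len(nrow(nodes)), nodes)
    skel <- new("RootSkeletonGraph", nodes = nodes,
                edges = matrix(as.integer(edges), ncol = 2),
                branches = br, voxelSize = v)
    mask <- .voxeliseSpheres((as.matrix(nodes[, c("x", "y", "z")]) - 0.5) * v,
                             pmax(nodes$radius_um, 0.87 * v), dims, v)
    # guarantee the exact centreline voxels are inside the root phase
    iv <- cbind(pmin(pmax(round(nodes$x), 1), dims[1]),
                pmin(pmax(round(nodes$y), 1), dims[2]),
                pmin(pmax(round(nodes$z), 1), dims[3]))
    mask[iv] <- TRUE
    list(skeleton = skel, mask = mask, seedVoxel = seed, truncated = truncated)
  })
}

#' SyntheticScene: a rendered scene plus its ground truth
#'
#' @slot volume the rendered \linkS4class{GreyVolume}.
#' @slot phases ground-truth \linkS4class{FourPhaseVolume} (recorded before
#'   PSF blurring and noise).
#' @slot grains grain table (x, y, z, r in um; kept/removed flags).
#' @slot skeleton exact \linkS4class{RootSkeletonGraph}.
#' @slot surfaceZ index of the first sand slice.
#' @slot seedVoxel seed position (voxel coordinates).
#' @slot config the generating \linkS4class{SceneConfig}.
#' @export
setClass("SyntheticScene", representation(
  volume = "GreyVolume", phases = "FourPhaseVolume", grains = "data.frame",
  skeleton = "RootSkeletonGraph", surfaceZ = "integer", seedVoxel = "numeric",
  config = "SceneConfig"))

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene\n  ")
  show(object@volume)
  cat("  ")
  show(object@phases)
})

#' Render a scene to a CT-like grey volume
#'
#' Assembles the four-phase ground truth (air / water / sand / root), then
#' assigns per-phase grey means, applies a Gaussian point-spread function
#' and adds Gaussian noise. The root is carved out of the pore space:
#' grains intersecting the root tube are removed and recorded. Water is
#' geometric: full saturation below the water table plus pendular water at
#' grain contacts within the capillary fringe.
#'
#' @param pack output of \code{\link{generateGrainPack}}.
#' @param root output of \code{\link{generateRootSystem}}.
#' @param config the shared \linkS4class{SceneConfig}.
#' @return A \linkS4class{SyntheticScene}.
#' @export
renderScene <- function(pack, root, config) {
  dims <- pack$dims
  v <- config@voxelSize
  zsurf <- pack$surfaceZ
  g <- pack$grains
  keep <- g$kept
  # the root displaces grains: grains swallowed by the tube are removed,
  # grains straddling its surface are shrunk until they sit against it
  # (no free annulus is left around the root body)
  g$removed_by_root <- FALSE
  g$shrunk_by_root <- FALSE
  if (any(root$mask)) {
    rootDist <- distanceTransform(root$mask) * v   # um to root phase
    gi <- cbind(pmin(pmax(round(g$x / v + 0.5), 1), dims[1]),
                pmin(pmax(round(g$y / v + 0.5), 1), dims[2]),
                pmin(pmax(round(g$z / v + 0.5), 1), dims[3]))
    dr <- rootDist[gi]
    hit <- keep & (dr <= g$r + 0.5 * v)
    swallow <- hit & (dr <= pmax(0.4 * g$r, 0.5 * v))
    shrink <- hit & !swallow
    g$r[shrink] <- pmax(dr[shrink] - 0.2 * v, 0.3 * g$r[shrink])
    keep <- keep & !swallow
    g$removed_by_root <- swallow
    g$shrunk_by_root <- shrink
  }
  g$kept <- keep
  solid <- .voxeliseSpheres(as.matrix(g[keep, c("x", "y", "z")]),
                            g$r[keep], dims, v)
  solid <- solid & !root$mask
  labels <- array(0L, dims)
  labels[solid] <- 2L
  labels[root$mask] <- 3L
  # seed kernel: a dense ellipsoid at the seed position, drawn over the
  # root (root tissue inside the kernel is not resolvable); it also blocks
  # any air path between the emerging root and the headspace (the zone
  # above the seed is excluded from porosity analyses anyway)
  sv <- root$seedVoxel
  rr <- config@rootRadius / v
  ax <- 2.5 * rr; az <- 3 * rr
  i0 <- max(1, floor(sv[1] - ax)); i1 <- min(dims[1], ceiling(sv[1] + ax))
  j0 <- max(1, floor(sv[2] - ax)); j1 <- min(dims[2], ceiling(sv[2] + ax))
  k0 <- max(1, floor(sv[3] - rr - az)); k1 <- min(dims[3], ceiling(sv[3] - rr + az))
  ell <- outer(outer(((i0:i1) - sv[1])^2 / ax^2,
                     ((j0:j1) - sv[2])^2 / ax^2, "+"),
               ((k0:k1) - (sv[3] - rr))^2 / az^2, "+") <= 1
  sub <- labels[i0:i1, j0:j1, k0:k1]
  sub[ell] <- 2L
  labels[i0:i1, j0:j1, k0:k1] <- sub
  # water: below table fully saturated; contact films in the fringe
  if (is.finite(config@waterTableDepth)) {
    zarr <- array(rep(seq_len(dims[3]), each = prod(dims[1:2])), dims)
    ztab <- zsurf + config@waterTableDepth * 1000 / v
    pore <- labels == 0L & zarr > zsurf
    water <- pore & zarr >= ztab
    if (config@capillaryFringe > 0 && any(solid)) {
      # pendular bridges: pore voxels hugging grain surfaces inside narrow
      # throats (high local solid fraction), within the capillary band
      # (sub-voxel menisci smeared to voxel scale)
      dsand <- distanceTransform(solid)
      sfrac <- boxSum3d(array(as.numeric(solid), dims), 2L) / 125
      fringe <- pore & zarr >= ztab - config@capillaryFringe * 1000 / v &
        zarr < ztab & dsand <= 1.05 & sfrac >= 0.62
      water <- water | fringe
    }
    labels[water] <- 1L
  }
  phases <- fourPhaseVolume(labels, v)
  gm <- config@greyMeans
  grey <- array(gm[["air"]], dims)
  grey[labels == 1L] <- gm[["water"]]
  grey[labels == 2L] <- gm[["sand"]]
  grey[labels == 3L] <- gm[["root"]]
  if (config@psfSigma > 0) grey <- gaussianBlur3d(grey, config@psfSigma)
  if (config@noiseSigma > 0)
    grey <- grey + withSeed(config@rngSeed + 202L,
                            array(rnorm(length(grey), 0, config@noiseSigma), dims))
  new("SyntheticScene",
      volume = greyVolume(grey, v, 0L), phases = phases, grains = g,
      skeleton = root$skeleton, surfaceZ = as.integer(zsurf),
      seedVoxel = root$seedVoxel, config = config)
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper: grain pack + root system + rendering.
#' @param config a \linkS4class{SceneConfig}.
#' @return A \linkS4class{SyntheticScene}.
#' @export
synthScene <- function(config = sceneConfig()) {
  pack <- generateGrainPack(config)
  root <- generateRootSystem(config)
  renderScene(pack, root, config)
}

# trilinear sampling of a 3D array at fractional voxel coordinates
.trilinearSample <- function(a, xyz, background = NA_real_) {
  d <- dim(a)
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  out_of <- x < 1 | x > d[1] | y < 1 | y > d[2] | z < 1 | z > d[3]
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2])
  z <- pmin(pmax(z, 1), d[3])
  i0 <- pmin(floor(x), d[1] - 1); j0 <- pmin(floor(y), d[2] - 1)
  k0 <- pmin(floor(z), d[3] - 1)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  at <- function(i, j, k) a[cbind(i, j, k)]
  val <-
    at(i0,     j0,     k0)     * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i0 + 1, j0,     k0)     * fx       * (1 - fy) * (1 - fz) +
    at(i0,     j0 + 1, k0)     * (1 - fx) * fy       * (1 - fz) +
    at(i0 + 1, j0 + 1, k0)     * fx       * fy       * (1 - fz) +
    at(i0,     j0,     k0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(i0 + 1, j0,     k0 + 1) * fx       * (1 - fy) * fz +
    at(i0,     j0 + 1, k0 + 1) * (1 - fx) * fy       * fz +
    at(i0 + 1, j0 + 1, k0 + 1) * fx       * fy       * fz
  if (!is.na(background)) val[out_of] <- background
  attr(val, "out_of_bounds") <- out_of
  val
}

#' Warp a volume with a prescribed displacement field
#'
#' Deforms a grey volume by inverse mapping with trilinear interpolation
#' and returns, alongside the deformed volume, closed-form evaluators of
#' the displacement and (where defined) the transformation gradient, for
#' use as DIC and strain ground truth.
#'
#' Supported fields (all in voxel units):
#' \describe{
#'   \item{translation}{\code{params$t}: rigid shift vector.}
#'   \item{affine}{\code{params$F} (3x3) about \code{params$center}
#'     (defaults to the volume centre): \code{u(X) = (F - I)(X - c)}.}
#'   \item{radial}{\code{params$a}, \code{params$lambda}, about the
#'     vertical axis through \code{params$axis = c(cx, cy)}:
#'     \code{u_r(r) = a exp(-r / lambda)}, no vertical component.}
#' }
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param field one of "translation", "affine", "radial".
#' @param params named list of field parameters (voxel units).
#' @param background grey value used where material is mapped in from
#'   outside the image; the affected margin is flagged.
#' @return list with \code{deformed} (\linkS4class{GreyVolume}),
#'   \code{displacement(points)} (n x 3 matrix of voxel displacements at
#'   voxel-coordinate query points), \code{gradient(points)} (n x 3 x 3
#'   analytic F, or NULL for pure translation), and \code{margin} (logical
#'   array flagging background-filled voxels).
#' @export
warpScene <- function(volume, field = c("translation", "affine", "radial"),
                      params, background = NULL) {
  field <- match.arg(field)
  a <- volume@data
  d <- dim(a)
  if (is.null(background)) background <- min(a)
  disp <- switch(field,
    translation = {
      t0 <- params$t
      function(p) matrix(t0, nrow(p), 3, byrow = TRUE)
    },
    affine = {
      FF <- params$F
      ctr <- if (!is.null(params$center)) params$center else (d + 1) / 2
      function(p) {
        rel <- sweep(p, 2, ctr)
        rel %*% t(FF - diag(3))
      }
    },
    radial = {
      a0 <- params$a; lam <- params$lambda
      ax <- if (!is.null(params$axis)) params$axis else (d[1:2] + 1) / 2
      function(p) {
        dx <- p[, 1] - ax[1]; dy <- p[, 2] - ax[2]
        r <- sqrt(dx^2 + dy^2)
        ur <- a0 * exp(-r / lam)
        f <- ifelse(r > 1e-9, ur / r, 0)
        cbind(dx * f, dy * f, 0)
      }
    })
  grad <- switch(field,
    translation = NULL,
    affine = {
      FF <- params$F
      function(p) {
        out <- array(0, c(nrow(p), 3, 3))
        for (i in seq_len(nrow(p))) out[i, , ] <- FF
        out
      }
    },
    radial = {
      a0 <- params$a; lam <- params$lambda
      ax <- if (!is.null(params$axis)) params$axis else (d[1:2] + 1) / 2
      function(p) {
        dx <- p[, 1] - ax[1]; dy <- p[, 2] - ax[2]
        r <- pmax(sqrt(dx^2 + dy^2), 1e-9)
        ur <- a0 * exp(-r / lam)
        durdr <- -a0 / lam * exp(-r / lam)
        ex <- dx / r; ey <- dy / r
        out <- array(0, c(nrow(p), 3, 3))
        # grad u = u_r' e_r e_r^T + (u_r / r) e_t e_t^T  (plane field)
        out[, 1, 1] <- 1 + durdr * ex^2 + ur / r * ey^2
        out[, 2, 2] <- 1 + durdr * ey^2 + ur / r * ex^2
        out[, 1, 2] <- out[, 2, 1] <- (durdr - ur / r) * ex * ey
        out[, 3, 3] <- 1
        out
      }
    })
  # inverse mapping: find X with x = X + u(X)
  grid <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                z = seq_len(d[3])))
  X <- switch(field,
    translation = sweep(grid, 2, params$t),
    affine = {
      FF <- params$F
      ctr <- if (!is.null(params$center)) params$center else (d + 1) / 2
      sweep(sweep(grid, 2, ctr) %*% t(solve(FF)), 2, ctr, "+")
    },
    radial = {
      X <- grid
      for (it in 1:4) X <- grid - disp(X)
      X
    })
  val <- .trilinearSample(a, X, background = background)
  margin <- array(attr(val, "out_of_bounds"), d)
  deformed <- greyVolume(array(as.numeric(val), d), volume@voxelSize,
                         volume@dayIndex + 1L)
  list(deformed = deformed, displacement = disp, gradient = grad,
       margin = margin)
}
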