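#' Voxel size accessor
#'
#' @param x an object holding a voxel grid.
#' @return Voxel edge length in micrometres.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "GreyVolume", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "FourPhaseVolume", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "RootSkeletonGraph", function(x) x@voxelSize)

#' Grey data accessor
#' @param x a GreyVolume.
#' @return The 3D grey array.
#' @export
setGeneric("greyData", function(x) standardGeneric("greyData"))

#' @rdname greyData
#' @export
setMethod("greyData", "GreyVolume", function(x) x@data)

#' Phase label accessor
#' @param x a FourPhaseVolume.
#' @return Integer 3D array, 0 air / 1 water / 2 sand / 3 root.
#' @export
setGeneric("phaseLabels", function(x) standardGeneric("phaseLabels"))

#' @rdname phaseLabels
#' @export
setMethod("phaseLabels", "FourPhaseVolume", function(x) x@labels)

#' Per-phase voxel counts and volumes
#'
#' @param x a FourPhaseVolume.
#' @return data.frame with phase name, voxel count and volume in mm^3.
#' @export
setGeneric("phaseVolumes", function(x) standardGeneric("phaseVolumes"))

#' @rdname phaseVolumes
#' @export
setMethod("phaseVolumes", "FourPhaseVolume", function(x) {
  cnt <- tabulate(x@labels + 1L, nbins = 4L)
  vv <- (x@voxelSize * 1e-3)^3 # mm^3 per voxel
  data.frame(phase = c("air", "water", "sand", "root"),
             voxels = cnt, volume_mm3 = cnt * vv)
})

#' Skeleton branch table accessor
#' @param x a RootSkeletonGraph.
#' @return data.frame of branches (order, parent, length).
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))

#' @rdname branches
#' @export
setMethod("branches", "RootSkeletonGraph", function(x) x@branches)

#' Skeleton node table accessor
#' @param x a RootSkeletonGraph.
#' @return data.frame of nodes.
#' @export
setGeneric("skeletonNodes", function(x) standardGeneric("skeletonNodes"))

#' @rdname skeletonNodes
#' @export
setMethod("skeletonNodes", "RootSkeletonGraph", function(x) x@nodes)

setMethod("show", "GreyVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("GreyVolume %d x %d x %d, voxel %.1f um, day %d, grey [%.1f, %.1f]\n",
              d[1], d[2], d[3], object@voxelSize, object@dayIndex,
              min(object@data), max(object@data)))
})

setMethod("show", "FourPhaseVolume", function(object) {
  d <- dim(object@labels)
  pv <- phaseVolumes(object)
  cat(sprintf("FourPhaseVolume %d x %d x %d, voxel %.1f um\n",
              d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  %s: %d voxels (%.2f mm^3)\n", pv$phase, pv$voxels,
              pv$volume_mm3), sep = "")
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", paste(signif(object@peaks, 5), collapse = ", "),
      if (object@reference) "(reference)" else "", "\n")
})

setMethod("show", "RootSkeletonGraph", function(object) {
  cat(sprintf("RootSkeletonGraph: %d nodes, %d edges, %d branches\n",
              nrow(object@nodes), nrow(object@edges), nrow(object@branches)))
  if (nrow(object@branches)) {
    tot <- sum(object@branches$length_mm)
    cat(sprintf("  total length %.2f mm, orders: %s\n", tot,
                paste(sort(unique(object@branches$order)), collapse = ",")))
  }
})

setMethod("show", "DisplacementField", function(object) {
  tab <- table(object@status)
  cat(sprintf("DisplacementField: %d points (%s)\n", nrow(object@points),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
})

setMethod("show", "StrainField", function(object) {
  ok <- object@valid
  cat(sprintf("StrainField: %d points, %d valid\n", length(object@epsV),
              sum(ok)))
  if (any(ok))
    cat(sprintf("  eps_v in [%.4g, %.4g], eps_q in [%.4g, %.4g]\n",
                min(object@epsV[ok]), max(object@epsV[ok]),
                min(object@epsQ[ok]), max(object@epsQ[ok])))
})

setMethod("show", "PorosityProfile", function(object) {
  cat(sprintf("PorosityProfile (%s), day %d, %d bins\n", object@kind,
              object@dayIndex, nrow(object@table)))
})
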