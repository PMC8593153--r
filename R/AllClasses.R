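#' @import methods
NULL

#' GreyVolume: a 3D greyscale CT volume
#'
#' Container for a raw or pre-processed computed-tomography volume. The
#' array is indexed \code{[x, y, z]} with \code{z} increasing downwards
#' (depth); all physical lengths in this package are micrometres unless a
#' function documents otherwise.
#'
#' @slot data numeric 3D array of grey values.
#' @slot voxelSize voxel edge length in micrometres.
#' @slot dayIndex integer day of the chronosequence (day 0 = reference).
#' @export
setClass("GreyVolume",
  representation(data = "array", voxelSize = "numeric", dayIndex = "integer"),
  prototype(dayIndex = 0L)
)

setValidity("GreyVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || any(d < 1L)) return("data must be a non-empty 3D array")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0) return("voxelSize must be a single positive number")
  TRUE
})

#' Construct a GreyVolume
#'
#' @param data 3D numeric array, indexed \code{[x, y, z]}, z pointing down.
#' @param voxelSize voxel size in micrometres.
#' @param dayIndex day of the chronosequence.
#' @return A \linkS4class{GreyVolume}.
#' @export
greyVolume <- function(data, voxelSize, dayIndex = 0L) {
  new("GreyVolume", data = data, voxelSize = as.numeric(voxelSize),
      dayIndex = as.integer(dayIndex))
}

#' FourPhaseVolume: air/water/sand/root label image
#'
#' Voxelwise phase labels with the encoding 0 = air, 1 = water, 2 = sand,
#' 3 = root. Every voxel carries exactly one label.
#'
#' @slot labels integer 3D array with values in \code{0:3}.
#' @slot voxelSize voxel edge length in micrometres.
#' @export
setClass("FourPhaseVolume",
  representation(labels = "array", voxelSize = "numeric")
)

setValidity("FourPhaseVolume", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  r <- range(object@labels)
  if (r[1] < 0 || r[2] > 3) return("labels must be in 0:3 (air/water/sand/root)")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  TRUE
})

#' @rdname FourPhaseVolume-class
#' @param labels integer 3D array with values in 0:3.
#' @param voxelSize voxel size in micrometres.
#' @export
fourPhaseVolume <- function(labels, voxelSize) {
  storage.mode(labels) <- "integer"
  new("FourPhaseVolume", labels = labels, voxelSize = as.numeric(voxelSize))
}

#' PeakSet: grey-level histogram peaks
#'
#' Ordered grey values of the modes of a volume histogram, one per
#' distinguishable phase. Used to anchor the linear contrast stretch that
#' makes grey levels comparable across a chronosequence.
#'
#' @slot peaks strictly increasing numeric vector of peak grey values.
#' @slot reference logical; TRUE if these peaks define the reference day.
#' @export
setClass("PeakSet",
  representation(peaks = "numeric", reference = "logical"),
  prototype(reference = FALSE)
)

setValidity("PeakSet", function(object) {
  if (length(object@peaks) < 2L) return("need at least 2 peaks")
  if (any(diff(object@peaks) <= 0)) return("peaks must be strictly increasing")
  TRUE
})

#' @rdname PeakSet-class
#' @param peaks increasing numeric vector of peak grey values.
#' @param reference logical flag marking the reference day's peaks.
#' @export
peakSet <- function(peaks, reference = FALSE) {
  new("PeakSet", peaks = as.numeric(peaks), reference = reference)
}

#' RootSkeletonGraph: spatial graph of root centrelines
#'
#' One-voxel-wide centreline of a segmented root system, as a spatial graph.
#' Node positions are stored in (1-based, possibly fractional) voxel
#' coordinates together with a local radius estimate; branches are maximal
#' centreline paths between junctions/endpoints, labelled with a hierarchy
#' order (1 = primary axis, 2 = lateral, ...).
#'
#' @slot nodes data.frame with columns \code{node, x, y, z, radius_um,
#'   branch}.
#' @slot edges two-column integer matrix of node indices (undirected).
#' @slot branches data.frame with columns \code{branch, order, parent,
#'   length_mm, n_nodes}.
#' @slot voxelSize voxel size in micrometres.
#' @export
setClass("RootSkeletonGraph",
  representation(nodes = "data.frame", edges = "matrix",
                 branches = "data.frame", voxelSize = "numeric")
)

setValidity("RootSkeletonGraph", function(object) {
  if (nrow(object@nodes) == 0L) return("empty skeleton")
  need <- c("node", "x", "y", "z", "radius_um", "branch")
  if (!all(need %in% names(object@nodes)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  if (any(object@nodes$radius_um < 0)) return("node radii must be >= 0")
  if (nrow(object@branches) > 0 && any(object@branches$length_mm < 0))
    return("branch lengths must be >= 0")
  TRUE
})

#' DisplacementField: per-point displacement measurements
#'
#' Output of window DIC or particle tracking. Positions and displacements
#' are in millimetres; per-point status distinguishes converged
#' measurements from failed windows.
#'
#' @slot points n x 3 matrix of measurement positions (mm).
#' @slot displacements n x 3 matrix of displacement vectors (mm).
#' @slot status character vector, one of \code{converged},
#'   \code{poor_correlation}, \code{out_of_bounds}, \code{unmatched}.
#' @slot windowSide side length (mm) of the correlation window (NA for
#'   particle tracking).
#' @slot quality numeric per-point quality (peak NCC, or NA).
#' @export
setClass("DisplacementField",
  representation(points = "matrix", displacements = "matrix",
                 status = "character", windowSide = "numeric",
                 quality = "numeric")
)

setValidity("DisplacementField", function(object) {
  n <- nrow(object@points)
  if (nrow(object@displacements) != n || length(object@status) != n)
    return("points, displacements and status must agree in length")
  ok <- object@status == "converged"
  if (any(!is.finite(object@displacements[ok, , drop = FALSE])))
    return("converged displacements must be finite")
  TRUE
})

#' StrainField: per-point or per-tetrahedron strain measures
#'
#' Transformation gradients F and their invariants: volumetric strain
#' \code{eps_v = det(F) - 1} (dilation positive) and deviatoric strain
#' \code{eps_q} (norm of the traceless part of the small-strain tensor,
#' always >= 0).
#'
#' @slot points n x 3 matrix of evaluation positions (mm); window centres
#'   for grid strain, tetrahedron centroids for discrete strain.
#' @slot F n x 3 x 3 array of transformation gradients.
#' @slot epsV numeric volumetric strain per point.
#' @slot epsQ numeric deviatoric strain per point.
#' @slot support integer: neighbour count (grid) or tetrahedron vertex
#'   count/flag (discrete).
#' @slot valid logical; FALSE where the neighbourhood was degenerate.
#' @export
setClass("StrainField",
  representation(points = "matrix", F = "array", epsV = "numeric",
                 epsQ = "numeric", support = "integer", valid = "logical")
)

setValidity("StrainField", function(object) {
  if (any(object@epsQ[object@valid] < -1e-12, na.rm = TRUE))
    return("eps_q must be >= 0")
  if (any(object@epsV[object@valid] <= -1, na.rm = TRUE))
    return("eps_v must be > -1")
  TRUE
})

#' PorosityProfile: binned porosity versus depth or root distance
#'
#' @slot table data.frame with columns \code{lower_mm, upper_mm, mid_mm,
#'   porosity, voxel_count, low_support}.
#' @slot kind either "vertical" (depth bins) or "shell" (distance from the
#'   root surface).
#' @slot dayIndex integer day.
#' @export
setClass("PorosityProfile",
  representation(table = "data.frame", kind = "character",
                 dayIndex = "integer")
)

setValidity("PorosityProfile", function(object) {
  tb <- object@table
  if (nrow(tb) > 0) {
    if (any(tb$porosity < 0 | tb$porosity > 1, na.rm = TRUE))
      return("porosity must lie in [0, 1]")
    if (any(diff(tb$lower_mm) <= 0)) return("bins must be ordered")
  }
  TRUE
})
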