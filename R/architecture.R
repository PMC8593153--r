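# Root-system architecture: skeletonization, branch hierarchy and metrics.

#' Extract the centreline skeleton graph of a root mask
#'
#' Thins the root mask to a one-voxel-wide centreline (topological
#' peeling preserving endpoints), builds a 26-connectivity spatial graph,
#' prunes short spurs (thinning artefacts), and estimates a local radius at
#' every node from the Euclidean distance to the background; the root
#' cross-section size at a node is twice that radius.
#'
#' @param rootMask logical 3D array (the largest connected component is
#'   used; others are reported in a message).
#' @param voxelSize voxel size in micrometres.
#' @param pruneFactor spurs shorter than \code{pruneFactor} times the local
#'   radius (in voxels) are removed; default 3.
#' @return A \linkS4class{RootSkeletonGraph} (branch orders unset; see
#'   \code{\link{labelHierarchy}}).
#' @export
skeletonGraph <- function(rootMask, voxelSize, pruneFactor = 3) {
  stopifnot(is.logical(rootMask), length(dim(rootMask)) == 3L)
  if (!any(rootMask)) stop("empty root mask")
  d <- dim(rootMask)
  lab <- labelComponents(rootMask, 26L)
  sizes <- attr(lab, "sizes")
  if (length(sizes) > 1L) {
    message(sprintf("root mask has %d components; keeping the largest (%d voxels), dropping %d voxels",
                    length(sizes), max(sizes), sum(sizes) - max(sizes)))
    rootMask <- lab == which.max(sizes)
  }
  # local radius: distance to background, with half-voxel surface correction
  radius <- sqrt(cpp_edt_sq(as.vector(!rootMask), as.integer(d)))
  dim(radius) <- d
  skel <- cpp_thin3d(as.vector(rootMask), as.integer(d))
  dim(skel) <- d
  vox <- which(skel)
  ijk <- arrayInd(vox, d)
  n <- nrow(ijk)
  if (n == 0L) stop("thinning produced an empty skeleton")
  # 26-adjacency edges among skeleton voxels
  id <- array(0L, d)
  id[vox] <- seq_len(n)
  eds <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[order(offs[, 3], offs[, 2], offs[, 1]), , drop = FALSE]
  eList <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    q <- sweep(ijk, 2, offs[o, ], "+")
    ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
      q[, 3] >= 1 & q[, 3] <= d[3]
    tid <- integer(n)
    tid[ok] <- id[q[ok, , drop = FALSE]]
    sel <- tid > seq_len(n) # undirected, count once
    if (any(sel)) eList[[o]] <- cbind(which(sel), tid[sel])
  }
  eds <- do.call(rbind, eList)
  if (is.null(eds)) eds <- matrix(integer(0), 0, 2)
  g <- igraph::graph_from_edgelist(eds, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  elen <- sqrt(rowSums((ijk[eds[, 1], , drop = FALSE] -
                        ijk[eds[, 2], , drop = FALSE])^2))
  igraph::E(g)$weight <- elen
  rad_vox <- pmax(radius[vox] - 0.5, 0.5) # centre-to-surface, half-voxel bias removed
  # iterative spur pruning: remove endpoint paths shorter than the local cutoff
  repeat {
    deg <- igraph::degree(g)
    ends <- which(deg == 1L)
    junc <- which(deg >= 3L)
    if (!length(ends) || !length(junc)) break
    removed <- FALSE
    for (e in ends) {
      # walk from the endpoint to the nearest junction
      path <- e
      cur <- e
      prev <- 0L
      len <- 0
      repeat {
        nb <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (length(nb) != 1L) break
        len <- len + sqrt(sum((ijk[cur, ] - ijk[nb, ])^2))
        prev <- cur
        cur <- nb
        if (igraph::degree(g, cur) >= 3L) break
        path <- c(path, cur)
      }
      if (igraph::degree(g, cur) >= 3L && len < pruneFactor * rad_vox[e]) {
        g <- igraph::delete_edges(g, unique(unlist(igraph::incident_edges(g, path))))
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  # thinning retreats about one radius from tube tips: extend every
  # endpoint along its local direction until the mask boundary
  occ <- skel
  deg <- igraph::degree(g)
  for (e in which(deg == 1L)) {
    path <- e
    cur <- e
    prev <- 0L
    while (length(path) < 6L) {
      nb <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
      if (length(nb) != 1L) break
      prev <- cur
      cur <- nb[1]
      path <- c(path, cur)
    }
    if (length(path) < 2L) next
    dir <- ijk[path[1], ] - ijk[path[length(path)], ]
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) next
    dir <- dir / nrm
    last <- e
    maxt <- ceiling(3 * rad_vox[e]) + 2L
    for (t in seq_len(maxt)) {
      p <- round(ijk[e, ] + dir * t)
      if (any(p < 1) || any(p > d)) break
      if (!rootMask[p[1], p[2], p[3]]) break
      if (occ[p[1], p[2], p[3]]) break
      occ[p[1], p[2], p[3]] <- TRUE
      ijk <- rbind(ijk, p)
      rad_vox <- c(rad_vox, max(radius[p[1], p[2], p[3]] - 0.5, 0.5))
      g <- igraph::add_vertices(g, 1)
      nv <- igraph::vcount(g)
      g <- igraph::add_edges(g, c(last, nv),
                             attr = list(weight = sqrt(sum((ijk[nv, ] - ijk[last, ])^2))))
      last <- nv
    }
  }
  n <- nrow(ijk)
  keep <- igraph::degree(g) > 0 | n == 1L
  if (!any(keep)) keep[1] <- TRUE
  gsub <- igraph::induced_subgraph(g, which(keep))
  ijk2 <- ijk[keep, , drop = FALSE]
  rad2 <- rad_vox[keep]
  nodes <- data.frame(node = seq_len(sum(keep)),
                      x = ijk2[, 1], y = ijk2[, 2], z = ijk2[, 3],
                      radius_um = rad2 * voxelSize, branch = NA_integer_)
  e2 <- igraph::as_edgelist(gsub)
  storage.mode(e2) <- "integer"
  gb <- .branchDecompose(gsub, ijk2, voxelSize)
  nodes$branch <- gb$nodeBranch
  new("RootSkeletonGraph", nodes = nodes, edges = e2,
      branches = gb$branches, voxelSize = voxelSize)
}

# polyline length with light moving-average smoothing of the voxel
# positions (window 5, ends anchored) to suppress the staircase
# overestimation of digital centrelines
.pathLength <- function(p) {
  n <- nrow(p)
  if (n < 2L) return(0)
  if (n >= 5L) {
    sm <- p
    for (c in 1:3) {
      x <- p[, c]
      cs <- cumsum(c(0, x))
      i <- 3:(n - 2)
      sm[i, c] <- (cs[i + 3] - cs[i - 2]) / 5
    }
    p <- sm
  }
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2)))
}

# decompose a skeleton graph into maximal branch paths between
# junctions/endpoints; junction nodes belong to the first (parent) branch
# that claims them
.branchDecompose <- function(g, ijk, voxelSize) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  nodeBranch <- rep(NA_integer_, n)
  edgeSeen <- rep(FALSE, igraph::ecount(g))
  branchesL <- list()
  bid <- 0L
  terminals <- which(deg != 2L)
  if (!length(terminals)) terminals <- 1L # a pure cycle; start anywhere
  for (t in terminals) {
    for (nb in as.integer(igraph::neighbors(g, t))) {
      eid <- igraph::get_edge_ids(g, c(t, nb))
      if (edgeSeen[eid]) next
      path <- c(t, nb)
      edgeSeen[eid] <- TRUE
      cur <- nb
      prev <- t
      while (deg[cur] == 2L) {
        nxt <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)
        if (!length(nxt)) break
        eid <- igraph::get_edge_ids(g, c(cur, nxt[1]))
        if (edgeSeen[eid]) break
        edgeSeen[eid] <- TRUE
        path <- c(path, nxt[1])
        prev <- cur
        cur <- nxt[1]
      }
      bid <- bid + 1L
      len <- .pathLength(ijk[path, , drop = FALSE])
      branchesL[[bid]] <- data.frame(branch = bid, order = NA_integer_,
                                     parent = NA_integer_,
                                     length_mm = len * voxelSize * 1e-3,
                                     n_nodes = length(path))
      inner <- path[is.na(nodeBranch[path])]
      nodeBranch[inner] <- bid
      attr(branchesL[[bid]], "path") <- path
    }
  }
  branches <- do.call(rbind, branchesL)
  if (is.null(branches))
    branches <- data.frame(branch = 1L, order = NA_integer_,
                           parent = NA_integer_, length_mm = 0, n_nodes = n)
  attr(branches, "paths") <- lapply(branchesL, attr, "path")
  list(branches = branches, nodeBranch = nodeBranch)
}

#' Assign hierarchical branch orders
#'
#' Roots the skeleton at the node nearest the seed position and decomposes
#' it as a tree of axes: the primary axis (order 1) is the deepest-reaching
#' path from the root node (ties within 1\% depth broken towards the
#' longer path, with a warning); every subtree hanging off an order-k axis
#' becomes one order-(k+1) branch whose own axis is its farthest path from
#' the attachment node. Subtrees shorter than about two local diameters
#' are treated as thinning artefacts and absorbed into the parent.
#'
#' @param graph a \linkS4class{RootSkeletonGraph}.
#' @param seedPosition numeric (x, y, z) in voxel coordinates.
#' @return The graph with one branch row per axis, ordered and with
#'   parents filled in.
#' @export
labelHierarchy <- function(graph, seedPosition) {
  stopifnot(is(graph, "RootSkeletonGraph"))
  nd <- graph@nodes
  xyz <- as.matrix(nd[, c("x", "y", "z")])
  g <- igraph::graph_from_edgelist(graph@edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(nd))
    g <- igraph::add_vertices(g, nrow(nd) - igraph::vcount(g))
  w <- sqrt(rowSums((xyz[graph@edges[, 1], , drop = FALSE] -
                     xyz[graph@edges[, 2], , drop = FALSE])^2))
  igraph::E(g)$weight <- w
  start <- which.min(colSums((t(xyz) - seedPosition)^2))
  dists <- igraph::distances(g, v = start)[1, ]
  reach <- is.finite(dists)
  deg <- igraph::degree(g)
  tips <- which(deg <= 1L & reach)
  if (!length(tips)) tips <- which(reach)
  depth <- nd$z[tips]
  best <- max(depth)
  cand <- tips[depth >= best - 0.01 * max(best - nd$z[start], 1)]
  tip <- cand[1]
  if (length(cand) > 1L) {
    tip <- cand[which.max(dists[cand])]
    warning("ambiguous primary axis (two tips within 1% depth); choosing the longer path")
  }
  primary <- as.integer(igraph::shortest_paths(g, start, tip)$vpath[[1]])

  nodeBranch <- rep(NA_integer_, nrow(nd))
  branchRows <- list()
  paths <- list()
  nb <- 0L
  radius_vox <- nd$radius_um / graph@voxelSize

  addBranch <- function(axis, order, parent) {
    nb <<- nb + 1L
    nodeBranch[axis[is.na(nodeBranch[axis])]] <<- nb
    branchRows[[nb]] <<- data.frame(
      branch = nb, order = order, parent = parent,
      length_mm = .pathLength(xyz[axis, , drop = FALSE]) *
        graph@voxelSize * 1e-3,
      n_nodes = length(axis))
    paths[[nb]] <<- axis
    nb
  }

  # recursive axis decomposition of the rooted tree
  decompose <- function(axis, order, branchId) {
    inAxis <- rep(FALSE, nrow(nd))
    inAxis[axis] <- TRUE
    for (v in axis) {
      for (u in as.integer(igraph::neighbors(g, v))) {
        if (inAxis[u] || !is.na(nodeBranch[u])) next
        # subtree hanging off the axis at v, reached through u
        sub <- .subtreeNodes(g, v, u, inAxis, nodeBranch)
        if (!length(sub)) next
        dsub <- igraph::distances(g, v = v, to = sub,
                                  weights = igraph::E(g)$weight)[1, ]
        far <- sub[which.max(dsub)]
        childAxis <- as.integer(igraph::shortest_paths(g, v, far)$vpath[[1]])
        # artefact wiring lies inside the parent tube (thick local radius)
        # while a real lateral is its own thin tube: scale the absorb
        # cutoff by the subtree's own diameter
        diam <- 2 * mean(radius_vox[setdiff(childAxis, v)])
        if (max(dsub) < 2 * diam) {
          # artefact wiring: absorb into the parent branch, keeping its
          # centreline length in the parent's account
          nodeBranch[sub[is.na(nodeBranch[sub])]] <<- branchId
          branchRows[[branchId]]$length_mm <<-
            branchRows[[branchId]]$length_mm +
            .pathLength(xyz[childAxis, , drop = FALSE]) *
              graph@voxelSize * 1e-3
          next
        }
        child <- addBranch(childAxis, order + 1L, branchId)
        decompose(childAxis, order + 1L, child)
        # leftover subtree nodes not claimed recursively join the child
        left <- sub[is.na(nodeBranch[sub])]
        nodeBranch[left] <<- child
      }
    }
  }

  pid <- addBranch(primary, 1L, 0L)
  decompose(primary, 1L, pid)
  nodeBranch[is.na(nodeBranch)] <- pid

  br <- do.call(rbind, branchRows)
  attr(br, "paths") <- paths
  attr(br, "primary_nodes") <- primary
  out <- graph
  out@nodes$branch <- nodeBranch
  out@branches <- br
  out
}

# nodes of the subtree reached from v through u when the axis is removed
.subtreeNodes <- function(g, v, u, inAxis, nodeBranch) {
  seen <- c(v)
  stack <- u
  out <- integer(0)
  while (length(stack)) {
    x <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (x %in% seen) next
    seen <- c(seen, x)
    if (inAxis[x] || !is.na(nodeBranch[x])) next
    out <- c(out, x)
    nbs <- as.integer(igraph::neighbors(g, x))
    stack <- c(stack, setdiff(nbs, seen))
  }
  out
}

#' Architecture metrics
#'
#' Root length density, tip depth below the sand surface, lateral count,
#' primary-root length and day-to-day elongation rate.
#'
#' @param graph an order-labelled \linkS4class{RootSkeletonGraph}.
#' @param soilVolume_mm3 analysed soil volume in mm^3.
#' @param surfaceZ sand surface position (voxel index).
#' @param priorPrimaryLengths_mm primary lengths of preceding days (mm),
#'   oldest first, for the elongation rate.
#' @return list with \code{rld_m_per_m3}, \code{tip_depth_mm},
#'   \code{n_laterals}, \code{primary_length_mm}, \code{total_length_mm},
#'   \code{elongation_rate_mm_day}.
#' @export
architectureMetrics <- function(graph, soilVolume_mm3, surfaceZ = 0,
                                priorPrimaryLengths_mm = numeric(0)) {
  stopifnot(is(graph, "RootSkeletonGraph"), soilVolume_mm3 > 0)
  br <- graph@branches
  tot_mm <- sum(br$length_mm)
  rld <- unname((tot_mm * 1e-3) / (soilVolume_mm3 * 1e-9)) # m / m^3
  tip <- (max(graph@nodes$z) - surfaceZ) * graph@voxelSize * 1e-3
  nlat <- sum(br$order >= 2L, na.rm = TRUE)
  prim <- sum(br$length_mm[br$order == 1L], na.rm = TRUE)
  rate <- if (length(priorPrimaryLengths_mm))
    prim - tail(priorPrimaryLengths_mm, 1) else NA_real_
  list(rld_m_per_m3 = rld, tip_depth_mm = tip, n_laterals = nlat,
       primary_length_mm = prim, total_length_mm = tot_mm,
       elongation_rate_mm_day = rate)
}
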