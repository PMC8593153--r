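# Shared 3D image primitives. Heavy per-voxel work lives in src/; the
# separable operations (box sums, Gaussian blur) are vectorised here.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so seeded generators do not disturb the session.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Euclidean distance transform of a 3D mask
#'
#' Distance (in voxels) from every voxel to the nearest \code{TRUE} voxel
#' of \code{feature}. Exact squared-distance transform, separable scan.
#'
#' @param feature logical 3D array of feature voxels.
#' @param squared return squared distances if TRUE.
#' @return Numeric 3D array of distances (voxels); \code{Inf} when the mask
#'   is empty.
#' @export
distanceTransform <- function(feature, squared = FALSE) {
  stopifnot(is.logical(feature), length(dim(feature)) == 3L)
  d <- cpp_edt_sq(as.vector(feature), as.integer(dim(feature)))
  d[d >= 1e18] <- Inf # empty mask
  dim(d) <- dim(feature)
  if (squared) d else sqrt(d)
}

#' Connected-component labelling of a 3D mask
#'
#' @param mask logical 3D array.
#' @param conn connectivity, 6 or 26.
#' @return Integer array of component labels (0 = background), with an
#'   attribute \code{sizes} giving voxel counts per label.
#' @export
labelComponents <- function(mask, conn = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, conn %in% c(6L, 26L))
  lab <- cpp_label3d(as.vector(mask), as.integer(dim(mask)), as.integer(conn))
  dim(lab) <- dim(mask)
  n <- max(lab)
  attr(lab, "sizes") <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  lab
}

#' Morphological dilation / erosion by a Euclidean ball
#'
#' Implemented through the exact distance transform, which makes the
#' structuring element an isotropic digital ball of the given radius.
#'
#' @param mask logical 3D array.
#' @param radius ball radius in voxels.
#' @return Logical array.
#' @export
dilateMask <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  distanceTransform(mask, squared = TRUE) <= radius^2 + 1e-9
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  if (all(mask)) return(mask)
  distanceTransform(!mask, squared = TRUE) > radius^2 + 1e-9
}

# running box sum of half-width r along one axis, edge-clipped
.runBoxSum <- function(a, r, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  n <- dm[1]
  m <- matrix(m, nrow = n)
  cs <- apply(m, 2, cumsum)
  if (n == 1) cs <- matrix(cs, nrow = 1)
  csp <- rbind(0, cs)
  hi <- pmin(seq_len(n) + r, n)
  lo <- pmax(seq_len(n) - r, 1)
  res <- csp[hi + 1L, , drop = FALSE] - csp[lo, , drop = FALSE]
  dim(res) <- dm
  aperm(res, order(perm))
}

#' Box-filter sum over a cubic window
#'
#' Sum of values in the cubic window of half-width \code{r} centred at each
#' voxel, with windows clipped at the image edges. Separable cumulative-sum
#' implementation.
#' @param a numeric 3D array.
#' @param r window half-width in voxels.
#' @return Numeric array of window sums.
#' @export
boxSum3d <- function(a, r) {
  stopifnot(length(dim(a)) == 3L, r >= 0)
  for (ax in 1:3) a <- .runBoxSum(a, r, ax)
  a
}

#' Separable Gaussian blur of a 3D array
#'
#' Edge-clipped (renormalised) Gaussian convolution, used as the synthetic
#' scanner point-spread function and for marker smoothing.
#' @param a numeric 3D array.
#' @param sigma standard deviation in voxels.
#' @return Blurred array.
#' @export
gaussianBlur3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-h):h)^2 / sigma^2)
  for (ax in 1:3) {
    d <- dim(a)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(a, perm)
    dm <- dim(m)
    n <- dm[1]
    # banded kernel matrix with edge renormalisation
    K <- matrix(0, n, n)
    for (off in (-h):h) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1 & j <= n
      K[cbind(idx[ok], j[ok])] <- k[off + h + 1]
    }
    K <- K / rowSums(K)
    m <- K %*% matrix(m, nrow = n)
    dim(m) <- dm
    a <- aperm(m, order(perm))
  }
  a
}

#' Otsu's threshold
#'
#' Maximises between-class variance on a 256-bin histogram of the values.
#' @param x numeric values.
#' @param nbins histogram bins.
#' @return Threshold on the scale of \code{x}.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# integer-voxel circular shift of a 3D array (used by tests and warps)
#' Circularly shift a 3D array by integer voxels
#' @param a 3D array.
#' @param s integer shift vector of length 3.
#' @return Shifted array.
#' @export
rollArray <- function(a, s) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    n <- d[ax]
    ((seq_len(n) - 1L - as.integer(s[ax])) %% n) + 1L
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# voxel centre coordinates (1-based index i -> physical (i - 0.5) * voxel um)
.voxGrid <- function(d) {
  list(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
}
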