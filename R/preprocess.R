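# Pre-processing: grey-level normalisation across a chronosequence,
# factor-2 downscaling, and edge-preserving denoising.

#' Find the most prominent grey-level histogram peaks
#'
#' Builds a unit-width grey histogram, smooths it with a fixed-width
#' Gaussian kernel (default sd 3 grey levels), and returns the \code{nPeaks}
#' most prominent local maxima sorted ascending. Prominence of a peak is
#' its height above the highest saddle separating it from a higher peak.
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param nPeaks number of peaks requested (one per phase mode).
#' @param smoothSigma histogram smoothing sd in grey levels.
#' @param reference mark the result as the reference day's peaks.
#' @return A \linkS4class{PeakSet}.
#' @export
findHistogramPeaks <- function(volume, nPeaks = 2L, smoothSigma = 3,
                               reference = FALSE) {
  stopifnot(is(volume, "GreyVolume"), nPeaks >= 1L)
  x <- as.vector(volume@data)
  r <- range(x)
  if (diff(r) < .Machine$double.eps)
    stop("histogram is degenerate (constant volume): no peaks found")
  br <- seq(floor(r[1]), ceiling(r[2]) + 1)  # unit-width bins
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                nbins = length(br) - 1L)
  mids <- br[-length(br)] + 0.5
  # Gaussian smoothing of the histogram
  hw <- max(1L, ceiling(3 * smoothSigma))
  k <- exp(-0.5 * ((-hw):hw)^2 / smoothSigma^2)
  k <- k / sum(k)
  hp <- c(rep(h[1], hw), h, rep(h[length(h)], hw))
  hs <- vapply(seq_along(h), function(i) sum(hp[i:(i + 2 * hw)] * k), 0)
  n <- length(hs)
  is_max <- hs > c(-Inf, hs[-n]) & hs >= c(hs[-1], -Inf)
  cand <- which(is_max & hs > 0)
  if (length(cand) < nPeaks)
    stop(sprintf("found only %d local maxima (at grey %s) but %d peaks requested",
                 length(cand), paste(signif(mids[cand], 4), collapse = ", "),
                 nPeaks))
  # prominence: height above the deepest saddle towards any higher peak
  prom <- vapply(cand, function(i) {
    higher <- cand[hs[cand] > hs[i]]
    if (!length(higher)) return(hs[i])
    saddles <- vapply(higher, function(j)
      min(hs[seq(min(i, j), max(i, j))]), 0)
    hs[i] - max(saddles)
  }, 0)
  top <- cand[order(prom, decreasing = TRUE)[seq_len(nPeaks)]]
  peakSet(sort(mids[top]), reference = reference)
}

#' Linear contrast stretch anchored on histogram peaks
#'
#' Applies the affine grey map through the first and last peak of
#' \code{peaks} onto the corresponding reference peaks, so that after the
#' stretch the peak grey values match the reference day exactly. Values are
#' clipped to the valid grey range; the number of clipped voxels is
#' recorded in the \code{clipped} attribute of the returned data.
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param peaks \linkS4class{PeakSet} of this volume.
#' @param reference \linkS4class{PeakSet} of the reference day.
#' @param greyRange valid output range, default \code{c(0, 65535)}.
#' @return The stretched \linkS4class{GreyVolume}.
#' @export
contrastStretch <- function(volume, peaks, reference,
                            greyRange = c(0, 65535)) {
  stopifnot(is(volume, "GreyVolume"), is(peaks, "PeakSet"),
            is(reference, "PeakSet"))
  p <- peaks@peaks; q <- reference@peaks
  if (length(p) != length(q) || length(p) < 2)
    stop("peak sets must have equal length >= 2")
  a1 <- p[1]; a2 <- p[length(p)]
  b1 <- q[1]; b2 <- q[length(q)]
  if (abs(a2 - a1) < .Machine$double.eps)
    stop("coincident anchor peaks: zero-gain stretch is undefined")
  gain <- (b2 - b1) / (a2 - a1)
  out <- b1 + (volume@data - a1) * gain
  nclip <- sum(out < greyRange[1] | out > greyRange[2])
  out <- pmin(pmax(out, greyRange[1]), greyRange[2])
  res <- greyVolume(array(out, dim(volume@data)), volume@voxelSize,
                    volume@dayIndex)
  attr(res@data, "clipped") <- nclip
  res
}

#' Downscale a volume by block averaging
#'
#' Isotropic binning by an integer factor: each output voxel is the mean of
#' a factor^3 block, so the voxel count drops by factor^3 and the voxel
#' size is multiplied by the factor (block means also denoise). Dimensions
#' not divisible by the factor are cropped to the largest divisible box
#' (reported via a message).
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param factor integer binning factor (>= 1).
#' @return The downscaled \linkS4class{GreyVolume}.
#' @export
downscale <- function(volume, factor = 2L) {
  stopifnot(is(volume, "GreyVolume"))
  f <- as.integer(factor)
  if (f < 1L) stop("factor must be >= 1")
  a <- volume@data
  d <- dim(a)
  if (any(d < f)) stop("factor larger than a volume dimension")
  if (f == 1L) return(volume)
  dd <- (d %/% f) * f
  if (any(dd != d)) {
    message(sprintf("cropping %s to %s for divisibility by %d",
                    paste(d, collapse = "x"), paste(dd, collapse = "x"), f))
    a <- a[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]), drop = FALSE]
  }
  dn <- dd %/% f
  dim(a) <- c(f, dn[1], f, dn[2], f, dn[3])
  out <- apply(a, c(2, 4, 6), mean)
  greyVolume(out, volume@voxelSize * f, volume@dayIndex)
}

#' Edge-preserving bilateral denoising
#'
#' 3D bilateral filter: Gaussian spatial weights times Gaussian grey-range
#' weights, so flat regions are smoothed while phase boundaries are kept.
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param sigmaSpatial spatial sd in voxels (default 2).
#' @param sigmaRange range sd in grey levels; the default is 3 x a robust
#'   noise estimate (median absolute voxel-to-voxel difference), capped at
#'   half the minimum inter-peak distance when \code{peaks} is given, so
#'   that noise is flattened but genuine phase edges are preserved.
#' @param peaks optional \linkS4class{PeakSet} used to cap the range sd.
#' @return The denoised \linkS4class{GreyVolume}.
#' @export
denoiseBilateral <- function(volume, sigmaSpatial = 2, sigmaRange = NULL,
                             peaks = NULL) {
  stopifnot(is(volume, "GreyVolume"), sigmaSpatial > 0)
  if (is.null(sigmaRange)) {
    a <- volume@data

    # noise floor: the low quantile of tiny-window variances sits in
    # homogeneous regions even when most of the image is granular texture
    v1 <- varianceFilter(a, 1L)
    noise <- sqrt(quantile(v1, 0.1, names = FALSE))
    sigmaRange <- 3 * noise
    if (!is.null(peaks))
      sigmaRange <- min(sigmaRange, min(diff(peaks@peaks)) / 2)
  }
  if (sigmaRange <= 0) stop("sigmaRange must be positive")
  out <- cpp_bilateral3d(as.vector(volume@data), as.integer(dim(volume@data)),
                         sigmaSpatial, sigmaRange)
  greyVolume(array(out, dim(volume@data)), volume@voxelSize, volume@dayIndex)
}
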