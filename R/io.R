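# Volume I/O: multi-page TIFF with a JSON sidecar carrying the metadata
# that TIFF does not (voxel size, day index, label encoding).

.sidecarPath <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Write a grey volume as 16-bit multi-page TIFF + JSON sidecar
#'
#' Grey values must lie in [0, 65535]; they are rounded to integers on
#' write, so integer-valued volumes round-trip bit-identically.
#'
#' @param volume a \linkS4class{GreyVolume}.
#' @param path output path (.tif); the sidecar goes next to it (.json).
#' @return \code{path}, invisibly.
#' @export
writeGreyVolume <- function(volume, path) {
  stopifnot(is(volume, "GreyVolume"))
  a <- volume@data
  if (min(a) < 0 || max(a) > 65535)
    stop("grey values must lie in [0, 65535] for 16-bit TIFF output")
  pages <- lapply(seq_len(dim(a)[3]), function(k)
    t(round(a[, , k])) / 65535) # TIFF pages are row-major (y, x)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(kind = "grey", voxel_size_um = volume@voxelSize,
                            day_index = volume@dayIndex, dims = dim(a),
                            bits = 16L),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grey volume written by \code{\link{writeGreyVolume}}
#'
#' @param path path to the TIFF; the JSON sidecar must sit next to it.
#' @return A \linkS4class{GreyVolume}.
#' @export
readGreyVolume <- function(path) {
  sc <- .sidecarPath(path)
  if (!file.exists(sc))
    stop("missing sidecar ", sc, " (voxel size unknown)")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_um) || !is.finite(meta$voxel_size_um))
    stop("sidecar does not provide a voxel size")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  if (!is.null(meta$dims) && !identical(as.integer(meta$dims), as.integer(d)))
    stop(sprintf("TIFF shape %s does not match sidecar dims %s",
                 paste(d, collapse = "x"), paste(meta$dims, collapse = "x")))
  a <- array(0, d)
  for (k in seq_len(d[3])) a[, , k] <- t(pages[[k]])
  greyVolume(a, meta$voxel_size_um,
             if (is.null(meta$day_index)) 0L else meta$day_index)
}

#' Write / read a four-phase label volume (8-bit TIFF + sidecar)
#'
#' @param phases a \linkS4class{FourPhaseVolume}.
#' @param path output .tif path.
#' @return \code{path}, invisibly.
#' @export
writePhaseVolume <- function(phases, path) {
  stopifnot(is(phases, "FourPhaseVolume"))
  a <- phases@labels
  pages <- lapply(seq_len(dim(a)[3]), function(k) t(a[, , k]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(kind = "phases", voxel_size_um = phases@voxelSize,
                            dims = dim(a),
                            encoding = list(air = 0, water = 1, sand = 2,
                                            root = 3)),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhaseVolume
#' @export
readPhaseVolume <- function(path) {
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  a <- array(0L, d)
  for (k in seq_len(d[3])) a[, , k] <- as.integer(t(pages[[k]]))
  fourPhaseVolume(a, meta$voxel_size_um)
}
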