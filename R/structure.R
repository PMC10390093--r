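#' Threshold a grayscale image into a mask
#'
#' @param image a \code{\linkS4class{GrayImage}}.
#' @param threshold numeric; voxels with value strictly greater than this
#'   are set.
#' @return A \code{\linkS4class{BinaryMask}}.
#' @export
binarize <- function(image, threshold = 0) {
  stopifnot(is(image, "GrayImage"), is.finite(threshold))
  BinaryMask(imageData(image) > threshold, voxelSpacing(image))
}

# shift a logical array along one axis, filling with FALSE
shiftLogical <- function(a, axis, by) {
  d <- dim(a)
  n <- d[axis]
  out <- array(FALSE, d)
  if (abs(by) >= n) return(out)
  src <- dst <- lapply(d, seq_len)
  if (by > 0) {
    dst[[axis]] <- (by + 1):n
    src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    dst[[axis]] <- 1:(n + by)
    src[[axis]] <- (1 - by):n
  }
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(a), src)))))
  out
}

#' Extract the boundary voxels of a mask
#'
#' A set voxel is a boundary voxel iff at least one of its face neighbours
#' (4-connectivity in 2D, 6-connectivity in 3D; voxels outside the array
#' count as unset) is unset.  Equivalently, the interior -- voxels whose
#' face neighbours are all set -- is removed, leaving a one-voxel-thick
#' outline.
#'
#' @param mask a nonempty \code{\linkS4class{BinaryMask}}.
#' @return A \code{\linkS4class{BinaryMask}} of the same shape.
#' @examples
#' sq <- BinaryMask(matrix(1, 5, 5))
#' nVoxels(extractBoundary(sq))  # 16 perimeter pixels
#' @export
extractBoundary <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  m <- maskData(mask)
  if (!any(m)) stop("cannot extract the boundary of an empty mask")
  interior <- m
  for (axis in seq_along(dim(m))) {
    interior <- interior & shiftLogical(m, axis, 1L) & shiftLogical(m, axis, -1L)
  }
  BinaryMask(m & !interior, voxelSpacing(mask))
}

#' Skeletonize a mask by topology-preserving thinning
#'
#' Shrinks each region to a 1-pixel-wide medial representation using
#' Zhang-Suen deletion conditions applied sequentially (each removed pixel
#' is a simple, non-endpoint point of the current image), followed by
#' simple-point removal of any residual 2x2 block.  Connected components
#' of the input map one-to-one onto components of the output; already-thin
#' inputs (single pixels, 1-pixel lines) are returned unchanged.
#'
#' 3D masks are thinned slice-by-slice along the third axis, matching the
#' per-slice reading of tumor cross-sections; see the package vignette.
#'
#' @param mask a nonempty \code{\linkS4class{BinaryMask}}.
#' @return A \code{\linkS4class{BinaryMask}} of the same shape.
#' @export
extractSkeleton <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  m <- maskData(mask)
  if (!any(m)) stop("cannot skeletonize an empty mask")
  if (length(dim(m)) == 2L) {
    out <- .thin2d(m)
  } else {
    out <- array(FALSE, dim(m))
    for (z in seq_len(dim(m)[3])) {
      if (any(m[, , z])) out[, , z] <- .thin2d(m[, , z])
    }
  }
  BinaryMask(out, voxelSpacing(mask))
}

#' Compute all three morphological aspects of a mask
#'
#' @param mask a nonempty \code{\linkS4class{BinaryMask}}.
#' @return An \code{\linkS4class{AspectSet}} with the general structure
#'   (the input), its boundary and its skeleton.
#' @export
extractAllAspects <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  new("AspectSet",
      general = mask,
      boundary = extractBoundary(mask),
      skeleton = extractSkeleton(mask))
}

#' Count connected components of a 2D mask
#'
#' @param mask a 2D \code{\linkS4class{BinaryMask}}.
#' @param connectivity 4 or 8 (default 8, the connectivity preserved by
#'   the thinning in \code{\link{extractSkeleton}}).
#' @return integer number of connected components.
#' @export
countComponents <- function(mask, connectivity = 8) {
  stopifnot(is(mask, "BinaryMask"), connectivity %in% c(4, 8))
  m <- maskData(mask)
  if (length(dim(m)) != 2L) stop("countComponents supports 2D masks only")
  max(.label2d(m, as.integer(connectivity)))
}
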