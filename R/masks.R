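#' Construct a BinaryMask
#'
#' Coerces any numeric/logical array to a mask by a nonzero test.
#'
#' @param data 2D or 3D array (logical or numeric; nonzero means set).
#' @param spacing optional per-axis voxel size in mm; default unit spacing.
#' @return A \code{\linkS4class{BinaryMask}}.
#' @examples
#' m <- BinaryMask(matrix(c(0, 1, 2, 0), 2, 2))
#' nVoxels(m)
#' @export
BinaryMask <- function(data, spacing = NULL) {
  if (is.null(dim(data))) stop("mask data must be an array, not a vector")
  d <- array(as.logical(data != 0), dim = dim(data))
  if (is.null(spacing)) spacing <- rep(1, length(dim(d)))
  new("BinaryMask", data = d, spacing = as.numeric(spacing))
}

#' Construct a GrayImage
#'
#' @param data 2D or 3D numeric array of finite intensities.
#' @param spacing optional per-axis voxel size in mm.
#' @return A \code{\linkS4class{GrayImage}}.
#' @export
GrayImage <- function(data, spacing = NULL) {
  if (is.null(dim(data))) stop("image data must be an array, not a vector")
  d <- array(as.numeric(data), dim = dim(data))
  if (is.null(spacing)) spacing <- rep(1, length(dim(d)))
  new("GrayImage", data = d, spacing = as.numeric(spacing))
}

#' @describeIn BinaryMask logical array payload of a mask.
#' @param x a \code{BinaryMask}.
#' @export
maskData <- function(x) {
  stopifnot(is(x, "BinaryMask"))
  x@data
}

#' @describeIn GrayImage numeric array payload of an image.
#' @param x a \code{GrayImage}.
#' @export
imageData <- function(x) {
  stopifnot(is(x, "GrayImage"))
  x@data
}

#' Voxel spacing of a mask or image
#' @param x a \code{BinaryMask} or \code{GrayImage}.
#' @return numeric vector of per-axis voxel sizes (mm).
#' @export
voxelSpacing <- function(x) x@spacing

#' Number of set voxels in a mask
#' @param x a \code{BinaryMask}.
#' @return integer count of set voxels.
#' @export
nVoxels <- function(x) sum(maskData(x))

#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@data))

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@data))

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %s | %d set voxel(s) | spacing %s mm\n",
              paste(dim(object@data), collapse = "x"),
              sum(object@data),
              paste(signif(object@spacing, 4), collapse = "x")))
})

setMethod("show", "GrayImage", function(object) {
  rng <- range(object@data)
  cat(sprintf("GrayImage %s | range [%g, %g]\n",
              paste(dim(object@data), collapse = "x"), rng[1], rng[2]))
})

setMethod("show", "AspectSet", function(object) {
  cat(sprintf("AspectSet %s | general %d, boundary %d, skeleton %d voxels\n",
              paste(dim(object@general@data), collapse = "x"),
              sum(object@general@data), sum(object@boundary@data),
              sum(object@skeleton@data)))
})

setMethod("show", "SyntheticCohort", function(object) {
  labs <- vapply(object@subjects, function(s) s$label, character(1))
  cat(sprintf("SyntheticCohort | %d subjects (LGG %d, HGG %d) | seed %d\n",
              length(labs), sum(labs == "LGG"), sum(labs == "HGG"),
              object@seed))
})

# run code under a seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
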