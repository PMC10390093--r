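#' Default geometric scale schedule for box counting
#'
#' Powers of \code{base} from 1 up to the largest power not exceeding half
#' the shortest axis of the structure's bounding box, which avoids the
#' degenerate regime where the whole object fits into one or two boxes.
#' Keying the upper scale to the object extent (rather than the canvas)
#' makes the estimate independent of how much empty background surrounds
#' the structure; for structures spanning the full array the two coincide.
#' At least three scales are always returned so a regression is possible
#' (a single-voxel mask gets \code{c(1, 2, 4)} and a flat count curve).
#'
#' @param mask a nonempty \code{\linkS4class{BinaryMask}} whose array is at
#'   least \code{2 * base} on every axis.
#' @param base integer, 2 or 3.
#' @return integer vector of box sides, e.g. \code{c(1, 2, 4, 8, 16, 32)}
#'   for a fully set 64 x 64 mask at base 2.
#' @export
defaultScales <- function(mask, base = 2) {
  stopifnot(is(mask, "BinaryMask"), base %in% c(2, 3))
  if (min(dim(mask)) < 2 * base)
    stop("mask too small for a base-", base,
         " scale schedule (shortest axis ", min(dim(mask)), " < ", 2 * base, ")")
  m <- maskData(mask)
  if (!any(m)) stop("cannot build a scale schedule for an empty mask")
  coords <- which(m, arr.ind = TRUE)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  extent <- apply(coords, 2, function(v) max(v) - min(v) + 1L)
  kmax <- max(2, floor(log(min(extent) / 2) / log(base) + 1e-9))
  as.integer(base^(0:kmax))
}

#' Box counting of a binary mask
#'
#' Covers the array with a grid of s-sided boxes anchored at the array
#' origin (conceptually zero-padding to a multiple of s) and counts, for
#' each scale, the boxes containing at least one set voxel.  A single
#' fixed grid is used -- no offset-minimization sweep.
#'
#' @param mask a nonempty \code{\linkS4class{BinaryMask}}.
#' @param scales integer vector of box sides; default
#'   \code{defaultScales(mask)}.
#' @return A \code{\linkS4class{BoxCountCurve}}.
#' @examples
#' sq <- genReferenceFractal("filled_square", 64)
#' counts(boxCount(sq))  # (64/s)^2 for s in 1,2,...,32
#' @export
boxCount <- function(mask, scales = defaultScales(mask)) {
  stopifnot(is(mask, "BinaryMask"))
  m <- maskData(mask)
  if (!any(m)) stop("cannot box-count an empty mask")
  scales <- as.integer(scales)
  coords <- which(m, arr.ind = TRUE)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  d <- dim(m)
  n <- vapply(scales, function(s) {
    box <- (coords - 1L) %/% s
    nb <- ceiling(d / s)
    id <- box[, 1]
    mult <- 1
    for (ax in seq_along(d)[-1]) {
      mult <- mult * nb[ax - 1]
      id <- id + mult * box[, ax]
    }
    length(unique(id))
  }, numeric(1))
  new("BoxCountCurve", scales = scales, counts = n)
}

#' @describeIn BoxCountCurve box sides of a curve.
#' @param x a \code{BoxCountCurve}.
#' @export
scales <- function(x) x@scales

#' @describeIn BoxCountCurve occupied-box counts of a curve.
#' @export
counts <- function(x) x@counts

setMethod("show", "BoxCountCurve", function(object) {
  cat("BoxCountCurve\n")
  print(data.frame(scale = object@scales, count = object@counts),
        row.names = FALSE)
})

#' Estimate fractal dimension from a box-counting curve
#'
#' Ordinary least squares of log10(N) on log10(S); the dimension D is the
#' negative slope (equivalently the slope against log10(1/S)).  A perfectly
#' flat curve (all counts equal, e.g. a single voxel) yields D = 0 with
#' r-squared 1 by convention, since the fit is exact.
#'
#' @param curve a \code{\linkS4class{BoxCountCurve}} with at least 3 scales.
#' @param aspect,region labels carried into the result.
#' @return An \code{\linkS4class{FDResult}}.
#' @examples
#' fdValue(fitFD(boxCount(genReferenceFractal("sierpinski_carpet", 5),
#'                        scales = 3^(0:4))))  # log(8)/log(3)
#' @export
fitFD <- function(curve, aspect = NA_character_, region = NA_character_) {
  stopifnot(is(curve, "BoxCountCurve"))
  ls <- log10(as.numeric(curve@scales))
  ln <- log10(curve@counts)
  k <- length(ls)
  if (k < 3L) stop("fractal-dimension fit requires at least 3 scales, got ", k)
  sxx <- sum((ls - mean(ls))^2)
  sxy <- sum((ls - mean(ls)) * (ln - mean(ln)))
  slope <- sxy / sxx
  intercept <- mean(ln) - slope * mean(ls)
  sst <- sum((ln - mean(ln))^2)
  sse <- sum((ln - (intercept + slope * ls))^2)
  r2 <- if (sst <= .Machine$double.eps) 1 else max(0, min(1, 1 - sse / sst))
  D <- -slope
  if (D == 0) D <- 0  # normalize negative zero from a flat fit
  new("FDResult", D = D, intercept = intercept, rSquared = r2,
      nScales = k, aspect = as.character(aspect), region = as.character(region))
}

#' @describeIn FDResult the estimated dimension D.
#' @param x an \code{FDResult}.
#' @export
fdValue <- function(x) x@D

#' @describeIn FDResult r-squared of the log-log fit.
#' @export
fdRSquared <- function(x) x@rSquared

setMethod("show", "FDResult", function(object) {
  cat(sprintf("FDResult [%s/%s] D = %.4f (r2 = %.4f, %d scales)\n",
              object@region, object@aspect, object@D, object@rSquared,
              object@nScales))
})

#' @export
setMethod("as.data.frame", "FDResult", function(x, ...) {
  data.frame(region = x@region, aspect = x@aspect, D = x@D,
             intercept = x@intercept, r_squared = x@rSquared,
             n_scales = x@nScales, stringsAsFactors = FALSE)
})

#' Box-counting FD of a single mask
#'
#' Convenience wrapper: default scale schedule, box counting, log-log fit.
#'
#' @inheritParams defaultScales
#' @param aspect,region labels carried into the result.
#' @return An \code{\linkS4class{FDResult}}.
#' @export
boxCountFD <- function(mask, base = 2, aspect = NA_character_,
                       region = NA_character_) {
  fitFD(boxCount(mask, defaultScales(mask, base)), aspect = aspect,
        region = region)
}

#' Fractal dimensions of the three aspects of one region
#'
#' @param aspects an \code{\linkS4class{AspectSet}}.
#' @param region region label propagated into each result.
#' @param base scale-schedule base (2 or 3).
#' @return list of three \code{\linkS4class{FDResult}} objects named
#'   general, boundary, skeleton.
#' @export
fdOfAspects <- function(aspects, region = NA_character_, base = 2) {
  stopifnot(is(aspects, "AspectSet"))
  lapply(stats::setNames(nm = c("general", "boundary", "skeleton")),
         function(a) {
    m <- slot(aspects, a)
    if (nVoxels(m) == 0L)
      missingFD(a, region)
    else
      boxCountFD(m, base = base, aspect = a, region = region)
  })
}

missingFD <- function(aspect, region) {
  new("FDResult", D = NA_real_, intercept = NA_real_, rSquared = NA_real_,
      nScales = 0L, aspect = aspect, region = region)
}

#' Fractal dimensions of one labelled region mask
#'
#' Computes general/boundary/skeleton FD; an empty mask (e.g. an LGG
#' subject without contrast enhancement) yields three missing-value
#' records instead of an error, which downstream statistics drop pairwise.
#'
#' @param mask a \code{\linkS4class{BinaryMask}} (possibly empty).
#' @param region region label.
#' @param base scale-schedule base.
#' @return list of three \code{\linkS4class{FDResult}} objects.
#' @export
regionFD <- function(mask, region = NA_character_, base = 2) {
  stopifnot(is(mask, "BinaryMask"))
  if (nVoxels(mask) == 0L) {
    lapply(stats::setNames(nm = c("general", "boundary", "skeleton")),
           missingFD, region = region)
  } else {
    fdOfAspects(extractAllAspects(mask), region = region, base = base)
  }
}
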