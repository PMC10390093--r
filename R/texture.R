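#' Quantize an image to 8-bit within a region
#'
#' Intensities inside the mask are linearly rescaled so the region minimum
#' maps to 0 and the maximum to 255, then rounded half-up to integers.
#' Constant regions map to 0.  Voxels outside the mask are set to 0 and are
#' never paired by \code{\link{computeGLCM}}.
#'
#' @param image a \code{\linkS4class{GrayImage}}.
#' @param mask a nonempty \code{\linkS4class{BinaryMask}} of the same shape.
#' @return A \code{\linkS4class{GrayImage}} with integer values in 0..255.
#' @export
quantize8bit <- function(image, mask) {
  stopifnot(is(image, "GrayImage"), is(mask, "BinaryMask"))
  if (!identical(dim(image), dim(mask))) stop("image and mask differ in shape")
  m <- maskData(mask)
  if (!any(m)) stop("cannot quantize over an empty mask")
  v <- imageData(image)
  inside <- v[m]
  rng <- max(inside) - min(inside)
  out <- array(0, dim(v))
  if (rng > 0) out[m] <- floor((v[m] - min(inside)) / rng * 255 + 0.5)
  GrayImage(out, voxelSpacing(image))
}

#' Gray-level co-occurrence matrix of a masked region
#'
#' Counts pairs of gray levels at a fixed displacement, requiring both
#' endpoints of every pair to lie inside the mask, and normalizes to a
#' joint probability matrix.  The default displacement is 1 pixel at 0
#' degrees (one step along the second array axis), asymmetric, with 256
#' levels -- the common texture-plugin defaults.
#'
#' @param image a quantized \code{\linkS4class{GrayImage}} with integer
#'   values in \code{0..levels-1} (see \code{\link{quantize8bit}}).
#' @param mask a \code{\linkS4class{BinaryMask}} of the same shape.
#' @param offset integer displacement vector, one entry per array axis;
#'   default \code{c(0, 1)} in 2D.
#' @param symmetric logical; if TRUE each pair is also counted reversed.
#' @param levels number of gray levels (default 256).
#' @return A \code{\linkS4class{GLCM}}.
#' @export
computeGLCM <- function(image, mask, offset = NULL, symmetric = FALSE,
                        levels = 256L) {
  stopifnot(is(image, "GrayImage"), is(mask, "BinaryMask"))
  if (!identical(dim(image), dim(mask))) stop("image and mask differ in shape")
  d <- dim(image)
  if (is.null(offset)) offset <- c(0L, 1L, rep(0L, length(d) - 2L))
  offset <- as.integer(offset)
  if (length(offset) != length(d)) stop("offset length must match dimensionality")
  levels <- as.integer(levels)
  v <- imageData(image)
  if (any(v[maskData(mask)] < 0) || any(v[maskData(mask)] > levels - 1))
    stop("image values must lie in 0..levels-1; quantize first")

  # index windows such that (i) and (i + offset) are both in-array
  src <- dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    o <- offset[ax]
    if (abs(o) >= d[ax]) stop("offset exceeds image extent on axis ", ax)
    if (o >= 0) { src[[ax]] <- 1:(d[ax] - o); dst[[ax]] <- (1 + o):d[ax] }
    else        { src[[ax]] <- (1 - o):d[ax]; dst[[ax]] <- 1:(d[ax] + o) }
  }
  a <- do.call(`[`, c(list(v), src))
  b <- do.call(`[`, c(list(v), dst))
  ma <- do.call(`[`, c(list(maskData(mask)), src))
  mb <- do.call(`[`, c(list(maskData(mask)), dst))
  keep <- ma & mb
  if (!any(keep)) stop("no valid pixel pairs inside the mask at this offset")
  i <- a[keep]
  j <- b[keep]
  tab <- matrix(0, levels, levels)
  cnt <- table(factor(i * levels + j, levels = 0:(levels^2 - 1)))
  tab[] <- as.numeric(cnt)
  tab <- t(tab)  # row = first pixel level i, col = second pixel level j
  if (symmetric) tab <- tab + t(tab)
  new("GLCM", matrix = tab / sum(tab), levels = levels, offset = offset,
      symmetric = symmetric)
}

setMethod("show", "GLCM", function(object) {
  cat(sprintf("GLCM %dx%d | offset (%s) | %s\n", object@levels, object@levels,
              paste(object@offset, collapse = ","),
              if (object@symmetric) "symmetric" else "asymmetric"))
})

#' Haralick features of a GLCM
#'
#' The five classical statistics: angular second moment (energy),
#' contrast, inverse difference moment (local homogeneity), correlation
#' and entropy (natural log).  Correlation is returned as NA when either
#' marginal has zero variance (e.g. a constant region).
#'
#' @param glcm a \code{\linkS4class{GLCM}}.
#' @return named numeric vector \code{c(asm, contrast, idm, correlation,
#'   entropy)}.
#' @examples
#' g <- new("GLCM", matrix = matrix(c(0, .5, .5, 0), 2), levels = 2L,
#'          offset = c(0L, 1L), symmetric = TRUE)
#' glcmFeatures(g)  # asm .5, contrast 1, idm .5, correlation -1, entropy log 2
#' @export
glcmFeatures <- function(glcm) {
  stopifnot(is(glcm, "GLCM"))
  p <- glcm@matrix
  L <- glcm@levels
  lev <- 0:(L - 1)
  i <- matrix(lev, L, L)       # row index = first pixel level
  j <- matrix(lev, L, L, byrow = TRUE)
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  pos <- p > 0
  entropy <- -sum(p[pos] * log(p[pos]))
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mui <- sum(lev * pi_)
  muj <- sum(lev * pj_)
  sdi <- sqrt(sum((lev - mui)^2 * pi_))
  sdj <- sqrt(sum((lev - muj)^2 * pj_))
  correlation <- if (sdi * sdj <= .Machine$double.eps) NA_real_
    else sum((i - mui) * (j - muj) * p) / (sdi * sdj)
  c(asm = asm, contrast = contrast, idm = idm, correlation = correlation,
    entropy = entropy)
}

#' Texture features of one labelled region
#'
#' Composition quantize -> GLCM -> Haralick features.  Empty regions (or
#' regions too small to form any pixel pair) yield an all-NA record rather
#' than an error, so a subject without contrast enhancement survives the
#' pipeline.
#'
#' @param image a \code{\linkS4class{GrayImage}}.
#' @param mask a \code{\linkS4class{BinaryMask}} of the same shape.
#' @param offset,symmetric,levels passed to \code{\link{computeGLCM}}.
#' @return named numeric vector of the five features (possibly all NA).
#' @export
regionTexture <- function(image, mask, offset = NULL, symmetric = FALSE,
                          levels = 256L) {
  stopifnot(is(image, "GrayImage"), is(mask, "BinaryMask"))
  empty <- c(asm = NA_real_, contrast = NA_real_, idm = NA_real_,
             correlation = NA_real_, entropy = NA_real_)
  if (nVoxels(mask) == 0L) return(empty)
  q <- quantize8bit(image, mask)
  g <- tryCatch(computeGLCM(q, mask, offset = offset, symmetric = symmetric,
                            levels = levels),
                error = function(e) NULL)
  if (is.null(g)) return(empty)
  glcmFeatures(g)
}
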