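#' Read a binary region mask from NIfTI or PNG
#'
#' Values are coerced to logical by a nonzero test, so label images
#' (e.g. 0/1/2) become TRUE wherever the label is nonzero.  Voxel spacing
#' is taken from the NIfTI header when present, else unit spacing.  An
#' all-false mask is accepted with a warning (analysis entry points reject
#' it); arrays with more than 3 dimensions are an error.
#'
#' @param path file path ending in .nii, .nii.gz or .png.
#' @return A \code{\linkS4class{BinaryMask}}.
#' @export
readMask <- function(path) {
  arr <- readImageArray(path)
  m <- BinaryMask(arr$data, arr$spacing)
  if (nVoxels(m) == 0L) warning("mask read from ", path, " has no set voxels")
  m
}

#' Read a grayscale image from NIfTI or PNG
#'
#' PNG intensities are returned on the 0-255 (8-bit) or 0-65535 (16-bit)
#' integer scale; NIfTI values are returned as stored.
#'
#' @param path file path ending in .nii, .nii.gz or .png.
#' @return A \code{\linkS4class{GrayImage}}.
#' @export
readGray <- function(path) {
  arr <- readImageArray(path)
  GrayImage(arr$data, arr$spacing)
}

readImageArray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
    # readPNG rescales to [0,1]; recover the integer bit-depth scale
    scale <- if (!is.null(info$bit.depth) && info$bit.depth == 16) 65535 else 255
    list(data = round(img * scale), spacing = NULL)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    nd <- length(dim(img))
    if (nd > 3L) stop("expected a 2D or 3D image, got ", nd, " dimensions: ", path)
    pd <- RNifti::pixdim(img)
    sp <- if (length(pd) >= nd && all(pd[seq_len(nd)] > 0)) pd[seq_len(nd)] else NULL
    list(data = array(as.numeric(img), dim = dim(img)), spacing = sp)
  } else stop("unsupported image format: ", path)
}

#' Write a mask to NIfTI or PNG
#'
#' Lossless: \code{readMask(writeMask(m, p))} reproduces the mask data
#' exactly.  PNG output is limited to 2D masks.
#'
#' @param mask a \code{\linkS4class{BinaryMask}}.
#' @param path destination (.nii, .nii.gz or .png).
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  writeImageArray(maskData(mask) * 1L, voxelSpacing(mask), path, maxval = 1)
}

#' Write a grayscale image to NIfTI or PNG
#'
#' PNG output quantizes to 8 bits on the 0-255 scale; NIfTI output is
#' lossless.
#'
#' @param image a \code{\linkS4class{GrayImage}}.
#' @param path destination (.nii, .nii.gz or .png).
#' @return \code{path}, invisibly.
#' @export
writeGray <- function(image, path) {
  stopifnot(is(image, "GrayImage"))
  writeImageArray(imageData(image), voxelSpacing(image), path, maxval = 255)
}

writeImageArray <- function(data, spacing, path, maxval) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (length(dim(data)) != 2L) stop("PNG output requires a 2D image")
    png::writePNG(pmin(pmax(data / maxval, 0), 1), path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(array(data, dim = dim(data)))
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' Write a feature/statistics table as CSV
#'
#' UTF-8, comma-delimited, '.' decimal separator, header always written
#' (an empty table yields a header-only file).
#'
#' @param rows a data.frame.
#' @param path destination .csv path.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Subtract the tumor region from a tissue mask
#'
#' Voxelwise set difference \code{tissue AND NOT tumor}, used to restrict
#' gray- and white-matter masks to non-tumorous brain before any fractal or
#' texture analysis.  Idempotent; the result never intersects the tumor.
#'
#' @param tissue,tumor \code{\linkS4class{BinaryMask}} objects of identical
#'   shape.
#' @return A \code{\linkS4class{BinaryMask}}.
#' @examples
#' a <- BinaryMask(matrix(1, 4, 4))
#' b <- BinaryMask(diag(4))
#' nVoxels(subtractRegion(a, b))  # 12
#' @export
subtractRegion <- function(tissue, tumor) {
  stopifnot(is(tissue, "BinaryMask"), is(tumor, "BinaryMask"))
  if (!identical(dim(tissue), dim(tumor)))
    stop("tissue and tumor masks differ in shape (",
         paste(dim(tissue), collapse = "x"), " vs ",
         paste(dim(tumor), collapse = "x"), ")")
  BinaryMask(maskData(tissue) & !maskData(tumor), voxelSpacing(tissue))
}
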