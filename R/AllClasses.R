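#' @useDynLib fracmorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Binary region mask
#'
#' A 2D or 3D boolean array with optional per-axis voxel spacing (mm).
#' This is the substrate for all morphological and fractal-dimension work:
#' segmented tumor subregions (whole tumor, enhanced tumor, edema) and
#' non-tumorous tissue regions (gray matter, white matter) are all carried
#' as \code{BinaryMask} objects.  Indexing is 0-based conceptually but the
#' stored array uses ordinary R 1-based indices; no world-coordinate math
#' is performed.
#'
#' @slot data logical array, 2 or 3 dimensions.
#' @slot spacing numeric vector, one positive value per axis (mm); defaults
#'   to unit spacing.
#' @export
setClass("BinaryMask",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    nd <- length(dim(object@data))
    if (!is.logical(object@data)) return("data must be a logical array")
    if (!(nd %in% c(2L, 3L))) return("mask must be 2D or 3D")
    if (length(object@spacing) != nd) return("spacing length must equal dimensionality")
    if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
      return("spacing must be positive and finite")
    TRUE
  }
)

#' Grayscale image
#'
#' A scalar 2D/3D array with the same geometry semantics as
#' \code{\linkS4class{BinaryMask}}.  Values are arbitrary finite reals on
#' read; texture analysis quantizes them to 8-bit internally.
#'
#' @slot data numeric array, 2 or 3 dimensions, finite values.
#' @slot spacing numeric vector of per-axis voxel sizes.
#' @export
setClass("GrayImage",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    nd <- length(dim(object@data))
    if (!is.numeric(object@data)) return("data must be a numeric array")
    if (!(nd %in% c(2L, 3L))) return("image must be 2D or 3D")
    if (any(!is.finite(object@data))) return("image values must be finite")
    if (length(object@spacing) != nd) return("spacing length must equal dimensionality")
    TRUE
  }
)

#' Box-counting curve
#'
#' Paired box sides S (voxels) and occupied-box counts N produced by
#' covering a mask with a grid of S-sided boxes anchored at the array
#' origin.  The log-log slope of this curve is the box-counting fractal
#' dimension.
#'
#' @slot scales integer vector of box sides, strictly increasing.
#' @slot counts numeric vector of occupied-box counts, same length,
#'   nonincreasing in scale (guaranteed for nested geometric schedules).
#' @export
setClass("BoxCountCurve",
  representation(scales = "integer", counts = "numeric"),
  validity = function(object) {
    s <- object@scales; n <- object@counts
    if (length(s) != length(n)) return("scales and counts differ in length")
    if (length(s) < 1L) return("curve must have at least one scale")
    if (any(s < 1L) || any(diff(s) <= 0L)) return("scales must be positive and strictly increasing")
    if (any(n < 1)) return("counts must be >= 1")
    if (any(diff(n) > 0)) return("counts must be nonincreasing in scale")
    TRUE
  }
)

#' Fractal-dimension estimate
#'
#' The result of an ordinary least-squares fit of log10 N against
#' log10 S over a box-counting curve: the dimension D is the negative
#' slope.  r-squared is always reported so that poor scaling regimes are
#' visible; a perfectly flat curve (all counts equal) is by convention
#' D = 0 with r-squared 1.
#'
#' @slot D numeric, estimated dimension (dimensionless); NA for a missing
#'   region.
#' @slot intercept numeric, base-10 intercept of the fit.
#' @slot rSquared numeric in [0, 1].
#' @slot nScales integer, number of scales used.
#' @slot aspect character, one of "general", "boundary", "skeleton".
#' @slot region character label.
#' @export
setClass("FDResult",
  representation(D = "numeric", intercept = "numeric", rSquared = "numeric",
                 nScales = "integer", aspect = "character", region = "character"))

#' The three morphological aspects of a mask
#'
#' General structure (the mask itself), boundary (set voxels with at least
#' one unset face-neighbour) and skeleton (topology-preserving thinning to
#' 1-voxel width).  Boundary and skeleton are always subsets of the general
#' structure.
#'
#' @slot general,boundary,skeleton \code{\linkS4class{BinaryMask}} objects
#'   of identical shape.
#' @export
setClass("AspectSet",
  representation(general = "BinaryMask", boundary = "BinaryMask",
                 skeleton = "BinaryMask"),
  validity = function(object) {
    g <- object@general@data; b <- object@boundary@data; k <- object@skeleton@data
    if (!identical(dim(g), dim(b)) || !identical(dim(g), dim(k)))
      return("aspects must share one shape")
    if (any(b & !g)) return("boundary must be a subset of the general structure")
    if (any(k & !g)) return("skeleton must be a subset of the general structure")
    TRUE
  }
)

#' Gray-level co-occurrence matrix
#'
#' Joint probability p(i, j) of observing gray levels i and j at a fixed
#' pixel displacement, with both endpoints of every counted pair inside the
#' region mask.  Gray levels are 0-based (row/column k holds level k - 1).
#'
#' @slot matrix L x L nonnegative matrix summing to 1.
#' @slot levels integer L (default 256 after 8-bit quantization).
#' @slot offset integer displacement vector (array-axis steps).
#' @slot symmetric logical; if TRUE pairs were counted in both directions.
#' @export
setClass("GLCM",
  representation(matrix = "matrix", levels = "integer", offset = "integer",
                 symmetric = "logical"),
  validity = function(object) {
    m <- object@matrix
    if (object@levels < 2L) return("levels must be >= 2")
    if (nrow(m) != object@levels || ncol(m) != object@levels)
      return("matrix must be levels x levels")
    if (any(m < 0)) return("entries must be nonnegative")
    if (abs(sum(m) - 1) > 1e-12) return("matrix must sum to 1")
    TRUE
  }
)

#' Synthetic two-group cohort
#'
#' A list of simulated subjects, each labelled LGG or HGG and carrying five
#' region masks (whole_tumor, enhanced_tumor, edema, gm, wm) and optionally
#' five textured grayscale images.  Enhanced tumor and edema are subsets of
#' the whole tumor; gm and wm are disjoint from it by construction.
#'
#' @slot subjects list; each element has \code{id}, \code{label},
#'   \code{seed}, \code{masks} (named list of \code{BinaryMask}) and
#'   \code{images} (named list of \code{GrayImage}, or NULL).
#' @slot params list, the full generator parameter record.
#' @slot seed integer master seed.
#' @export
setClass("SyntheticCohort",
  representation(subjects = "list", params = "list", seed = "integer"),
  validity = function(object) {
    regions <- c("whole_tumor", "enhanced_tumor", "edema", "gm", "wm")
    for (s in object@subjects) {
      if (!all(regions %in% names(s$masks)))
        return("every subject must carry all five region masks")
      if (!(s$label %in% c("LGG", "HGG"))) return("labels must be LGG or HGG")
    }
    TRUE
  }
)

#' Cross-validated classification report
#'
#' Metrics of a cross-validated SVM distinguishing LGG-like from HGG-like
#' subjects, averaged over resampling folds and reported on a 0-100 percent
#' scale.  HGG is the positive class for sensitivity/specificity.
#'
#' @slot featureSet character label of the feature subset used.
#' @slot kernel character, "linear", "poly" or "rbf".
#' @slot accuracy,sensitivity,specificity,auc numeric percentages in [0, 100].
#' @slot nFolds integer number of resampling folds.
#' @slot seed integer.
#' @slot foldMetrics data.frame of per-fold metrics (proportion scale).
#' @slot mode character, "repeated_split" or "kfold".
#' @export
setClass("ClassificationReport",
  representation(featureSet = "character", kernel = "character",
                 accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", auc = "numeric",
                 nFolds = "integer", seed = "integer",
                 foldMetrics = "data.frame", mode = "character"))
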