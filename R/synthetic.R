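#' Generate a reference shape with known fractal dimension
#'
#' Deterministic validation fixtures for the box-counting estimator:
#' iterated fractals whose box counts on the aligned scale schedule equal
#' the analytic self-similar counts exactly (Sierpinski carpet
#' \eqn{D = \log 8/\log 3}, Sierpinski triangle \eqn{D = \log 3/\log 2}),
#' plus space-filling and degenerate Euclidean cases (square D = 2,
#' line D = 1, point D = 0, disc).
#'
#' @param kind one of \code{"sierpinski_triangle"}, \code{"sierpinski_carpet"},
#'   \code{"filled_square"}, \code{"line"}, \code{"point"}, \code{"disc"}.
#' @param depthOrSize iteration depth for the two Sierpinski fractals
#'   (grid side \eqn{3^{depth}} for the carpet, \eqn{2^{depth}} for the
#'   triangle) or the grid side for the Euclidean shapes.
#' @param maxSide largest allowed grid side (guard against runaway depth).
#' @return A \code{\linkS4class{BinaryMask}}.
#' @examples
#' nVoxels(genReferenceFractal("sierpinski_carpet", 4))    # 8^4 = 4096
#' nVoxels(genReferenceFractal("sierpinski_triangle", 5))  # 3^5 = 243
#' @export
genReferenceFractal <- function(kind, depthOrSize, maxSide = 4096L) {
  kind <- match.arg(kind, c("sierpinski_triangle", "sierpinski_carpet",
                            "filled_square", "line", "point", "disc"))
  depthOrSize <- as.integer(depthOrSize)
  if (depthOrSize < 1L) stop("depthOrSize must be >= 1")
  side <- switch(kind,
                 sierpinski_carpet = 3L^depthOrSize,
                 sierpinski_triangle = 2L^depthOrSize,
                 depthOrSize)
  if (side > maxSide)
    stop("grid side ", side, " exceeds the configured maximum ", maxSide)
  m <- switch(kind,
    filled_square = matrix(TRUE, side, side),
    line = {
      z <- matrix(FALSE, side, side)
      z[(side + 1L) %/% 2L, ] <- TRUE
      z
    },
    point = {
      z <- matrix(FALSE, side, side)
      z[(side + 1L) %/% 2L, (side + 1L) %/% 2L] <- TRUE
      z
    },
    disc = {
      ctr <- (side + 1) / 2
      r <- side / 2 - 1
      row <- matrix(seq_len(side), side, side)
      col <- t(row)
      (row - ctr)^2 + (col - ctr)^2 <= r^2
    },
    sierpinski_triangle = {
      i <- matrix(0:(side - 1L), side, side)
      j <- t(i)
      matrix(bitwAnd(as.vector(i), as.vector(j)) == 0L, side, side)
    },
    sierpinski_carpet = {
      i <- as.vector(matrix(0:(side - 1L), side, side))
      j <- as.vector(t(matrix(0:(side - 1L), side, side)))
      keep <- rep(TRUE, side^2)
      for (k in 0:(depthOrSize - 1L)) {
        p <- 3L^k
        keep <- keep & !((i %/% p) %% 3L == 1L & (j %/% p) %% 3L == 1L)
      }
      matrix(keep, side, side)
    })
  BinaryMask(m)
}

# evaluate a random sum-of-sinusoids boundary perturbation, normalized to
# max |f| = 1 over the circle; returns a function of angle theta
radialPerturbation <- function(nHarmonics) {
  w <- abs(stats::rnorm(nHarmonics)) / seq_len(nHarmonics)^0.5
  phase <- stats::runif(nHarmonics, 0, 2 * pi)
  # tabulate one period on a fine grid; per-pixel lookup is then O(1)
  # (grid step 2*pi/16384 keeps the radius error below 0.1 px)
  nbin <- 16384L
  grid <- seq(0, 2 * pi, length.out = nbin + 1L)[-(nbin + 1L)]
  tab <- 0
  for (k in seq_len(nHarmonics)) tab <- tab + w[k] * sin(k * grid + phase[k])
  norm <- max(abs(tab))
  if (norm <= 0) norm <- 1
  tab <- tab / norm
  function(theta) tab[(floor((theta %% (2 * pi)) / (2 * pi) * nbin) %% nbin) + 1L]
}

# distance / angle grids about the canvas centre (fixed per canvas size)
.gridCache <- new.env(parent = emptyenv())
brainGrids <- function(size) {
  key <- as.character(size)
  if (is.null(.gridCache[[key]])) {
    bctr <- (size + 1) / 2
    row <- matrix(seq_len(size), size, size)
    col <- t(row)
    .gridCache[[key]] <- list(
      bd = sqrt((col - bctr)^2 + (row - bctr)^2),
      th = atan2(row - bctr, col - bctr))
  }
  .gridCache[[key]]
}

# stamp a small disc of radius rad at (x, y) into logical matrix m
stampDisc <- function(m, x, y, rad) {
  n <- nrow(m)
  p <- ncol(m)
  r0 <- max(1L, floor(y - rad)); r1 <- min(n, ceiling(y + rad))
  c0 <- max(1L, floor(x - rad)); c1 <- min(p, ceiling(x + rad))
  if (r0 > r1 || c0 > c1) return(m)
  rows <- r0:r1
  cols <- c0:c1
  dd <- outer((rows - y)^2, (cols - x)^2, `+`)
  m[rows, cols] <- m[rows, cols] | (dd <= rad^2)
  m
}

#' Generate a tumor-like binary mask
#'
#' A star-shaped region around a centre, with the boundary radius modulated
#' by a random sum of sinusoids (the well-circumscribed vs irregular
#' contrast: amplitude 0 gives a smooth disc with boundary FD near 1,
#' larger amplitudes give progressively rougher, higher-FD boundaries),
#' optionally with random-walk branch protrusions grown outward from the
#' boundary (mimicking infiltrative growth).  The result is always a
#' single connected component, and is deterministic given the seed.
#'
#' @param size canvas side in pixels (default 256).
#' @param baseRadius mean radius in pixels.
#' @param roughnessAmplitude relative boundary perturbation, in [0, 1].
#' @param roughnessFrequency integer >= 1, number of sinusoid harmonics.
#' @param nBranches integer >= 0, number of branch protrusions.
#' @param branchLength branch random-walk length in pixels.
#' @param center optional c(x, y) centre; default canvas centre.
#' @param seed integer RNG seed.
#' @return A \code{\linkS4class{BinaryMask}}.
#' @export
genTumorMask <- function(size = 256L, baseRadius = 40,
                         roughnessAmplitude = 0, roughnessFrequency = 8L,
                         nBranches = 0L, branchLength = 30,
                         center = NULL, seed = 1L) {
  checkShapeParams(baseRadius, roughnessAmplitude, roughnessFrequency,
                   nBranches, branchLength)
  withSeed(seed, {
    parts <- tumorMaskParts(size, baseRadius, roughnessAmplitude,
                            roughnessFrequency, nBranches, branchLength,
                            center)
    if (!any(parts$whole)) stop("tumor mask generation produced an empty mask")
    BinaryMask(parts$whole)
  })
}

checkShapeParams <- function(baseRadius, roughnessAmplitude,
                             roughnessFrequency, nBranches, branchLength) {
  if (baseRadius <= 0 || branchLength <= 0) stop("length parameters must be positive")
  if (roughnessAmplitude < 0 || roughnessAmplitude > 1)
    stop("roughnessAmplitude must lie in [0, 1]")
  if (roughnessFrequency < 1) stop("roughnessFrequency must be >= 1")
  if (nBranches < 0) stop("nBranches must be >= 0")
  invisible(TRUE)
}

# build the whole-tumor mask and the per-pixel radial field (used by
# genCohort to derive concentric enhanced-core / edema-shell subregions)
tumorMaskParts <- function(size, baseRadius, roughnessAmplitude,
                           roughnessFrequency, nBranches, branchLength,
                           center = NULL) {
  size <- as.integer(size)
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  cx <- center[1]; cy <- center[2]
  # radial fields are only needed on the window the tumor can reach
  reach <- baseRadius * (1 + roughnessAmplitude) +
    (if (nBranches > 0) branchLength + 3 else 0) + 2
  rows <- max(1L, floor(cy - reach)):min(size, ceiling(cy + reach))
  cols <- max(1L, floor(cx - reach)):min(size, ceiling(cx + reach))
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  distW <- sqrt(dx^2 + dy^2)
  pert <- if (roughnessAmplitude > 0)
    radialPerturbation(as.integer(roughnessFrequency)) else function(theta) 0
  rfieldW <- baseRadius * (1 + roughnessAmplitude * pert(atan2(dy, dx)))
  dist <- matrix(Inf, size, size)
  dist[rows, cols] <- distW
  rfield <- matrix(0, size, size)
  rfield[rows, cols] <- rfieldW
  whole <- dist <= rfield
  if (nBranches > 0) {
    branchAngles <- stats::runif(nBranches, 0, 2 * pi)
    for (b in seq_len(nBranches)) {
      ang <- branchAngles[b]
      # start just inside the actual boundary radius at this angle
      rb <- max(2, baseRadius * (1 + roughnessAmplitude * pert(ang)))
      x <- cx + rb * 0.9 * cos(ang)
      y <- cy + rb * 0.9 * sin(ang)
      dirn <- ang + stats::rnorm(1, 0, 0.2)
      for (t in seq_len(round(branchLength))) {
        x <- x + cos(dirn)
        y <- y + sin(dirn)
        dirn <- dirn + stats::rnorm(1, 0, 0.25)
        x <- min(max(x, 2), size - 1)
        y <- min(max(y, 2), size - 1)
        whole <- stampDisc(whole, x, y, 1.6)
      }
    }
  }
  list(whole = whole, dist = dist, rfield = rfield)
}

#' Generate a textured grayscale interior for a region
#'
#' Fills the mask with a spatially structured intensity pattern: a mixture
#' of a smooth (Gaussian-blurred) random field and a fine-scale
#' pixel-decorrelated component, mixed with weight
#' \code{contrastLevel / (1 + contrastLevel)} on the fine component.
#' Because 8-bit quantization rescales intensities to the region range,
#' it is this fine-scale variance share -- not the raw amplitude -- that
#' GLCM contrast and entropy respond to, and both increase monotonically
#' with \code{contrastLevel}.  At \code{contrastLevel = 0} and
#' \code{noiseSd = 0} the interior is constant.  Background is zero.
#'
#' @param mask a nonempty \code{\linkS4class{BinaryMask}}.
#' @param contrastLevel nonnegative; 0 gives a structureless interior.
#' @param noiseSd nonnegative SD of additive white noise (intensity units).
#' @param seed integer RNG seed.
#' @return A \code{\linkS4class{GrayImage}} with values in [0, 255],
#'   zero outside the mask.
#' @export
genTexturedRegion <- function(mask, contrastLevel = 1, noiseSd = 0,
                              seed = 1L) {
  stopifnot(is(mask, "BinaryMask"))
  if (contrastLevel < 0 || noiseSd < 0)
    stop("contrastLevel and noiseSd must be nonnegative")
  m <- maskData(mask)
  if (!any(m)) stop("cannot texture an empty mask")
  d <- dim(m)
  withSeed(seed, {
    out <- array(0, d)
    if (contrastLevel > 0 || noiseSd > 0) {
      fine <- array(stats::rnorm(prod(d)), d)
      smooth <- blurArray(array(stats::rnorm(prod(d)), d), sigma = 6)
      normIn <- function(a) {
        s <- stats::sd(a[m])
        if (!is.finite(s) || s <= 0) s <- 1
        a / s
      }
      lam <- contrastLevel / (1 + contrastLevel)
      pattern <- if (contrastLevel > 0)
        45 * ((1 - lam) * normIn(smooth) + lam * normIn(fine)) else 0
      noise <- if (noiseSd > 0) noiseSd * array(stats::rnorm(prod(d)), d) else 0
      vals <- 128 + pattern + noise
      out[m] <- pmin(pmax(round(vals[m]), 0), 255)
    } else {
      out[m] <- 128
    }
    GrayImage(out, voxelSpacing(mask))
  })
}

blurArray <- function(a, sigma) {
  d <- dim(a)
  if (length(d) == 2L) {
    EBImage::gblur(a, sigma = sigma)
  } else {
    for (z in seq_len(d[3])) a[, , z] <- EBImage::gblur(a[, , z], sigma = sigma)
    a
  }
}

#' Two-group effect parameters for cohort simulation
#'
#' Encodes the LGG-like (smaller, well-circumscribed, sparse thin-rim
#' enhancement with low texture contrast) versus HGG-like (larger,
#' rough-bordered, branched, solid high-contrast enhancement) conditions.
#' \code{enhFill} is the solidity of the enhancing core: 1 fills it
#' completely, small values leave only a thin enhancing rim, reproducing
#' the low mass dimension of sparse low-grade enhancement.  \code{separation} linearly
#' interpolates the HGG parameters between the LGG values (0, the null
#' configuration with zero planted group difference) and the full defaults
#' (1).
#'
#' @param separation numeric in [0, 1].
#' @return nested list of group parameters; SDs must be nonnegative
#'   (validated by \code{\link{genCohort}}).
#' @export
cohortEffect <- function(separation = 1) {
  stopifnot(separation >= 0, separation <= 1)
  lgg <- list(radiusMean = 30, radiusSd = 4, roughnessMean = 0.10,
              roughnessSd = 0.05, frequency = 6, branchMean = 0.3,
              branchLength = 15, enhContrast = 0.5, enhFill = 0.15)
  hggFull <- list(radiusMean = 48, radiusSd = 5, roughnessMean = 0.55,
                  roughnessSd = 0.10, frequency = 14, branchMean = 6,
                  branchLength = 28, enhContrast = 4, enhFill = 1)
  hgg <- mapply(function(a, b) a + separation * (b - a), lgg, hggFull,
                SIMPLIFY = FALSE)
  hgg$frequency <- round(hgg$frequency)
  list(lgg = lgg, hgg = hgg,
       shared = list(otherContrast = 1, noiseSd = 2, enhScale = 0.55,
                     edemaScale = 0.8, brainRadius = 110, gmThickness = 14,
                     centerJitter = 12))
}

#' Simulate a two-group tumor cohort
#'
#' Generates \code{nLGG + nHGG} subjects, each with the five region masks
#' (whole_tumor, enhanced_tumor, edema, gm, wm) and, optionally, textured
#' grayscale images per region.  The enhanced core and edema shell are
#' radially scaled copies of the whole-tumor field, so
#' enhanced_tumor and edema are subsets of whole_tumor by construction;
#' gm/wm are ring- and disc-shaped brain-tissue masks with the tumor
#' subtracted, so they never intersect it.  Per-subject sub-seeds are
#' drawn once from the master seed, so any subject is reproducible in
#' isolation from its recorded seed.
#'
#' @param nLGG,nHGG group sizes, each >= 2 (study default 27 and 15).
#' @param effect parameter list from \code{\link{cohortEffect}}.
#' @param seed master integer seed.
#' @param size canvas side in pixels.
#' @param textures logical; generate grayscale images (TRUE) or masks only.
#' @return A \code{\linkS4class{SyntheticCohort}}.
#' @export
genCohort <- function(nLGG = 27L, nHGG = 15L, effect = cohortEffect(),
                      seed = 1L, size = 256L, textures = TRUE) {
  if (nLGG < 2L || nHGG < 2L) stop("each group needs at least 2 subjects")
  for (g in c("lgg", "hgg")) {
    if (effect[[g]]$radiusSd < 0 || effect[[g]]$roughnessSd < 0)
      stop("degenerate effect parameters: SDs must be nonnegative")
  }
  n <- nLGG + nHGG
  labels <- c(rep("LGG", nLGG), rep("HGG", nHGG))
  subSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- simulateSubject(
      id = sprintf("%s%02d", labels[i], i),
      label = labels[i],
      group = effect[[tolower(labels[i])]],
      shared = effect$shared,
      size = size, seed = subSeeds[i], textures = textures)
  }
  new("SyntheticCohort", subjects = subjects,
      params = list(effect = effect, size = size, nLGG = nLGG, nHGG = nHGG,
                    textures = textures),
      seed = as.integer(seed))
}

simulateSubject <- function(id, label, group, shared, size, seed, textures) {
  # brain geometry is expressed for the reference 256 px canvas; rescale so
  # smaller canvases still hold the full gm ring and wm disc
  sc <- size / 256
  shared$brainRadius <- shared$brainRadius * sc
  shared$gmThickness <- shared$gmThickness * sc
  shared$centerJitter <- shared$centerJitter * sc
  withSeed(seed, {
    radius <- max(10, stats::rnorm(1, group$radiusMean, group$radiusSd))
    amp <- min(1, max(0, stats::rnorm(1, group$roughnessMean, group$roughnessSd)))
    nb <- stats::rpois(1, group$branchMean)
    ctr <- (size + 1) / 2 + stats::runif(2, -shared$centerJitter,
                                         shared$centerJitter)
    parts <- tumorMaskParts(size, radius, amp, group$frequency, nb,
                            group$branchLength, center = ctr)
    whole <- parts$whole
    # enhancement solidity: 1 = solid enhancing core (high-grade pattern),
    # small values = thin enhancing rim of the core (low-grade pattern)
    fill <- min(1, max(0.05, stats::rnorm(1, group$enhFill, 0.05)))
    enhOuter <- shared$enhScale * parts$rfield
    enhanced <- parts$dist <= enhOuter & parts$dist > (1 - fill) * enhOuter
    edema <- whole & !(parts$dist <= shared$edemaScale * parts$rfield)

    # brain envelope: wobbly outer ring (gm) around a deep-tissue disc (wm)
    bg <- brainGrids(size)
    bd <- bg$bd
    wob <- radialPerturbation(5L)(bg$th)
    outerR <- shared$brainRadius * (1 + 0.04 * wob)
    innerR <- (shared$brainRadius - shared$gmThickness) * (1 + 0.05 * wob)
    gm <- (bd <= outerR) & !(bd <= innerR) & !whole
    wm <- (bd <= innerR) & !whole

    masks <- list(whole_tumor = BinaryMask(whole),
                  enhanced_tumor = BinaryMask(enhanced),
                  edema = BinaryMask(edema),
                  gm = BinaryMask(gm),
                  wm = BinaryMask(wm))
    images <- NULL
    if (textures) {
      contrasts <- list(
        whole_tumor = shared$otherContrast,
        enhanced_tumor = group$enhContrast * exp(stats::rnorm(1, 0, 0.2)),
        edema = shared$otherContrast,
        gm = shared$otherContrast,
        wm = shared$otherContrast)
      regionSeeds <- sample.int(.Machine$integer.max - 1L, length(masks))
      images <- mapply(function(mk, cl, sd2) {
        if (nVoxels(mk) == 0L) return(NULL)
        genTexturedRegion(mk, contrastLevel = cl, noiseSd = shared$noiseSd,
                          seed = sd2)
      }, masks, contrasts[names(masks)], regionSeeds, SIMPLIFY = FALSE)
    }
    list(id = id, label = label, seed = seed, masks = masks, images = images)
  })
}

#' @describeIn genCohort number of subjects in a cohort.
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @export
nSubjects <- function(cohort) length(cohort@subjects)

#' @describeIn genCohort list of subject records.
#' @export
cohortSubjects <- function(cohort) cohort@subjects

#' Write a synthetic cohort to disk
#'
#' Masks and images as NIfTI, plus a CSV manifest (subject_id, label,
#' region, kind, path).
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in cohort@subjects) {
    for (rg in names(s$masks)) {
      p <- file.path(dir, paste0(s$id, "_", rg, "_mask.nii.gz"))
      writeMask(s$masks[[rg]], p)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$id, label = s$label, region = rg, kind = "mask",
        path = p, stringsAsFactors = FALSE)
      if (!is.null(s$images[[rg]])) {
        pi2 <- file.path(dir, paste0(s$id, "_", rg, "_image.nii.gz"))
        writeGray(s$images[[rg]], pi2)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$id, label = s$label, region = rg, kind = "image",
          path = pi2, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  writeTable(do.call(rbind, rows), manifest)
  invisible(manifest)
}
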