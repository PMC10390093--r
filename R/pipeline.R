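TUMOR_REGIONS <- c("whole_tumor", "enhanced_tumor", "edema")
TISSUE_REGIONS <- c("gm", "wm")
ALL_REGIONS <- c(TUMOR_REGIONS, TISSUE_REGIONS)
ASPECTS <- c("general", "boundary", "skeleton")
TEXTURE_FEATURES <- c("asm", "contrast", "idm", "correlation", "entropy")

#' Study configuration
#'
#' Collects every tunable of the pipeline in one declarative record:
#' cohort sizes and effect parameters for simulation, the box-counting
#' scale base, GLCM settings, cross-validation mode and the master seed.
#' Unknown fields are rejected so typos fail loudly.
#'
#' @param nLGG,nHGG simulated group sizes.
#' @param effect effect parameters (see \code{\link{cohortEffect}}).
#' @param seed master seed; all stage seeds derive from it.
#' @param size canvas side for simulation.
#' @param base box-counting scale base (2 or 3).
#' @param glcmOffset GLCM displacement (2D), default 1 pixel at 0 degrees.
#' @param glcmSymmetric logical.
#' @param cvMode "repeated_split" or "kfold".
#' @param nSplits resampling repeats / folds.
#' @param trainFrac training fraction for repeated splits.
#' @param subtractTumor subtract the whole tumor from gm/wm before
#'   analysis (idempotent; the simulator already guarantees disjointness).
#' @return a classed list.
#' @export
studyConfig <- function(nLGG = 27L, nHGG = 15L, effect = cohortEffect(),
                        seed = 7L, size = 256L, base = 2L,
                        glcmOffset = c(0L, 1L), glcmSymmetric = FALSE,
                        cvMode = "repeated_split", nSplits = 5L,
                        trainFrac = 0.7, subtractTumor = TRUE) {
  if (!base %in% c(2, 3)) stop("config field 'base' must be 2 or 3")
  if (!cvMode %in% c("repeated_split", "kfold"))
    stop("config field 'cvMode' must be 'repeated_split' or 'kfold'")
  if (trainFrac <= 0 || trainFrac >= 1)
    stop("config field 'trainFrac' must lie in (0, 1)")
  structure(list(nLGG = as.integer(nLGG), nHGG = as.integer(nHGG),
                 effect = effect, seed = as.integer(seed),
                 size = as.integer(size), base = as.integer(base),
                 glcmOffset = as.integer(glcmOffset),
                 glcmSymmetric = glcmSymmetric, cvMode = cvMode,
                 nSplits = as.integer(nSplits), trainFrac = trainFrac,
                 subtractTumor = subtractTumor),
            class = "studyConfig")
}

#' Extract the full feature row of one subject
#'
#' 15 FD features (general/boundary/skeleton of the three tumor regions
#' and the two non-tumorous tissue regions, the tumor having been
#' subtracted from gm/wm first) and 25 GLCM texture features (five per
#' region).  Empty regions -- e.g. no contrast enhancement -- produce NA
#' for their 3 FD and 5 texture entries rather than an error.  The result
#' is deterministic given the inputs.
#'
#' @param masks named list of \code{\linkS4class{BinaryMask}} over the
#'   five regions whole_tumor, enhanced_tumor, edema, gm, wm.
#' @param images optional named list of \code{\linkS4class{GrayImage}}
#'   per region; if NULL, texture features are NA.
#' @param config a \code{\link{studyConfig}}.
#' @return named numeric vector of length 40 (fd_* then tex_*).
#' @export
extractSubjectFeatures <- function(masks, images = NULL,
                                   config = studyConfig()) {
  if (!all(ALL_REGIONS %in% names(masks)))
    stop("masks must cover the regions: ", paste(ALL_REGIONS, collapse = ", "))
  if (all(vapply(masks[ALL_REGIONS], nVoxels, integer(1)) == 0L))
    stop("all regions empty: subject skipped")
  if (isTRUE(config$subtractTumor)) {
    for (rg in TISSUE_REGIONS)
      masks[[rg]] <- subtractRegion(masks[[rg]], masks$whole_tumor)
  }
  fd <- unlist(lapply(ALL_REGIONS, function(rg) {
    res <- regionFD(masks[[rg]], region = rg, base = config$base)
    stats::setNames(vapply(res, fdValue, numeric(1)),
                    paste0("fd_", rg, "_", ASPECTS))
  }))
  tex <- unlist(lapply(ALL_REGIONS, function(rg) {
    v <- if (is.null(images) || is.null(images[[rg]]))
      stats::setNames(rep(NA_real_, 5L), TEXTURE_FEATURES)
    else
      regionTexture(images[[rg]], masks[[rg]], offset = config$glcmOffset,
                    symmetric = config$glcmSymmetric)
    stats::setNames(v, paste0("tex_", rg, "_", TEXTURE_FEATURES))
  }))
  c(fd, tex)
}

#' Feature table of a whole cohort
#'
#' One row per subject: subject_id, label, 15 FD + 25 texture columns.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}} (or a list of
#'   subject records with the same structure).
#' @param config a \code{\link{studyConfig}}.
#' @return data.frame with 42 columns (id + label + 40 features).
#' @export
cohortFeatureTable <- function(cohort, config = studyConfig()) {
  subjects <- if (is(cohort, "SyntheticCohort")) cohort@subjects else cohort
  rows <- lapply(subjects, function(s) {
    feats <- extractSubjectFeatures(s$masks, s$images, config)
    cbind(data.frame(subject_id = s$id, label = s$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(feats)))
  })
  do.call(rbind, rows)
}

#' Run the full study on a simulated cohort
#'
#' Simulation, feature extraction, family-wise FDR-corrected group
#' statistics, and cross-validated SVM classification: each single FD
#' feature is ranked by best-kernel AUC, and the pooled FD and texture
#' feature sets are classified as groups.  Re-running with an identical
#' config reproduces identical outputs.
#'
#' @param config a \code{\link{studyConfig}}.
#' @param outDir optional directory; if given, features.csv,
#'   stats_fd.csv, stats_texture.csv and classification.csv/.json are
#'   written there.
#' @return list of class \code{"studyReport"}: \code{features} (the
#'   cohort table), \code{statsFD}, \code{statsTexture},
#'   \code{classification} (data.frame, one row per feature set),
#'   \code{reports} (the \code{ClassificationReport} objects),
#'   \code{config}.
#' @export
runStudy <- function(config = studyConfig(), outDir = NULL) {
  stopifnot(inherits(config, "studyConfig"))
  cohort <- genCohort(config$nLGG, config$nHGG, effect = config$effect,
                      seed = config$seed, size = config$size)
  features <- cohortFeatureTable(cohort, config)
  stats <- summarizeCohort(features)
  statsFD <- stats[stats$family == "fd", ]
  statsTexture <- stats[stats$family == "texture", ]

  labels <- features$label
  cvSeed <- config$seed + 1L
  fdCols <- grep("^fd_", names(features), value = TRUE)
  texCols <- grep("^tex_", names(features), value = TRUE)
  singleReports <- lapply(fdCols, function(f) {
    # a feature missing for most subjects (e.g. no enhancement anywhere)
    # cannot be cross-validated; skip it rather than abort the study
    tryCatch(
      selectBestKernel(features[, f, drop = FALSE], labels, seed = cvSeed,
                       mode = config$cvMode, nSplits = config$nSplits,
                       trainFrac = config$trainFrac, featureSet = f),
      error = function(e) {
        warning("feature ", f, " skipped: ", conditionMessage(e))
        NULL
      })
  })
  singleReports <- Filter(Negate(is.null), singleReports)
  # texture correlation can be NA for structureless regions; keep complete
  # columns so the pooled sets retain all subjects
  completeCols <- function(cols) cols[colSums(is.na(features[cols])) == 0]
  groupReports <- list(
    selectBestKernel(features[, completeCols(fdCols), drop = FALSE], labels,
                     seed = cvSeed, mode = config$cvMode,
                     nSplits = config$nSplits, trainFrac = config$trainFrac,
                     featureSet = "all_fd"),
    selectBestKernel(features[, completeCols(texCols), drop = FALSE], labels,
                     seed = cvSeed, mode = config$cvMode,
                     nSplits = config$nSplits, trainFrac = config$trainFrac,
                     featureSet = "all_texture"))
  reports <- c(singleReports, groupReports)
  classification <- do.call(rbind, lapply(reports, reportMetrics))

  out <- structure(list(features = features, statsFD = statsFD,
                        statsTexture = statsTexture,
                        classification = classification,
                        reports = reports, config = config),
                   class = "studyReport")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTable(features, file.path(outDir, "features.csv"))
    writeTable(statsFD, file.path(outDir, "stats_fd.csv"))
    writeTable(statsTexture, file.path(outDir, "stats_texture.csv"))
    writeTable(classification, file.path(outDir, "classification.csv"))
    jsonlite::write_json(classification,
                         file.path(outDir, "classification.json"),
                         dataframe = "rows", digits = NA)
  }
  out
}

#' @export
print.studyReport <- function(x, ...) {
  cat(sprintf("Study report: %d subjects, %d FD + %d texture features\n",
              nrow(x$features), nrow(x$statsFD), nrow(x$statsTexture)))
  sig <- x$statsFD$feature[x$statsFD$significant]
  cat("FDR-significant FD features:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  cl <- x$classification[x$classification$feature_set %in%
                           c("all_fd", "all_texture") |
                           startsWith(x$classification$feature_set, "fd_"), ]
  top <- cl[order(-cl$auc), ][1, ]
  cat(sprintf("Top feature set by AUC: %s (%s kernel, AUC %.1f%%)\n",
              top$feature_set, top$kernel, top$auc))
  invisible(x)
}
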