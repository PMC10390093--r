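#' Area under the ROC curve by rank statistics
#'
#' Equals the normalized Mann-Whitney U statistic:
#' P(score_pos > score_neg) + 0.5 P(tie), computed from midranks, so ties
#' contribute one half.
#'
#' @param scores numeric classifier scores, higher meaning more HGG-like.
#' @param labels logical or factor/character; TRUE / "HGG" is positive.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
  pos <- isPositive(labels)
  npos <- sum(pos)
  nneg <- sum(!pos)
  if (npos == 0L || nneg == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

isPositive <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  if (!all(labels %in% c("LGG", "HGG")))
    stop("labels must be logical or LGG/HGG")
  labels == "HGG"
}

# stratified resampling plans; labels logical (TRUE = positive)
makeSplits <- function(pos, mode, nSplits, trainFrac, seed) {
  idxPos <- which(pos)
  idxNeg <- which(!pos)
  withSeed(seed, {
    if (mode == "repeated_split") {
      lapply(seq_len(nSplits), function(k) {
        train <- c(sample(idxPos, max(1L, round(trainFrac * length(idxPos)))),
                   sample(idxNeg, max(1L, round(trainFrac * length(idxNeg)))))
        list(train = sort(train),
             test = sort(setdiff(c(idxPos, idxNeg), train)))
      })
    } else {
      foldOf <- integer(length(pos))
      foldOf[idxPos] <- sample(rep_len(seq_len(nSplits), length(idxPos)))
      foldOf[idxNeg] <- sample(rep_len(seq_len(nSplits), length(idxNeg)))
      lapply(seq_len(nSplits), function(k) {
        list(train = which(foldOf != k), test = which(foldOf == k))
      })
    }
  })
}

# fit an SVM on the training rows (standardized by training statistics
# only) and score the test rows; returns per-fold metrics
evalFold <- function(x, pos, split, kernel, cost) {
  tr <- split$train
  te <- split$test
  if (length(unique(pos[te])) < 2L || length(unique(pos[tr])) < 2L)
    return(NULL)  # degenerate fold
  mu <- colMeans(x[tr, , drop = FALSE])
  sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  yf <- factor(ifelse(pos, "HGG", "LGG"), levels = c("LGG", "HGG"))
  ek <- c(linear = "linear", poly = "polynomial", rbf = "radial")[kernel]
  fit <- e1071::svm(xs[tr, , drop = FALSE], yf[tr], kernel = unname(ek),
                    cost = cost, gamma = 1 / ncol(x), scale = FALSE,
                    probability = FALSE)
  pr <- stats::predict(fit, xs[te, , drop = FALSE], decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # orient decision values so larger means HGG
  scoreHGG <- if (grepl("^HGG", colnames(dv)[1])) dv[, 1] else -dv[, 1]
  predPos <- pr == "HGG"
  truePos <- pos[te]
  data.frame(
    accuracy = mean(predPos == truePos),
    sensitivity = sum(predPos & truePos) / sum(truePos),
    specificity = sum(!predPos & !truePos) / sum(!truePos),
    auc = rocAUC(scoreHGG, truePos))
}

#' Cross-validated SVM classification of tumor grade
#'
#' Stratified resampling with features standardized using training-fold
#' statistics only (no information leaks from test folds).  The default
#' resampling is 5 repeated stratified 70/30 train/test splits; plain
#' stratified 5-fold CV is available via \code{mode = "kfold"}.  Metrics
#' (accuracy, sensitivity, specificity, AUC; HGG positive) are averaged
#' over folds and reported as percentages.
#'
#' @param features numeric matrix or data.frame, one row per subject.
#' @param labels logical or LGG/HGG vector; HGG is the positive class.
#' @param kernel \code{"linear"}, \code{"poly"} or \code{"rbf"}.
#' @param seed integer seed controlling the resampling plan.
#' @param mode \code{"repeated_split"} (default) or \code{"kfold"}.
#' @param nSplits number of repeats / folds (default 5).
#' @param trainFrac training fraction for repeated splits (default 0.7).
#' @param cost SVM regularization parameter (default 1).
#' @param featureSet label carried into the report.
#' @param splits optional precomputed resampling plan (used by
#'   \code{\link{selectBestKernel}} to share folds across kernels).
#' @return A \code{\linkS4class{ClassificationReport}}.
#' @export
crossValidatedSVM <- function(features, labels, kernel = "linear",
                              seed = 1L, mode = c("repeated_split", "kfold"),
                              nSplits = 5L, trainFrac = 0.7, cost = 1,
                              featureSet = "features", splits = NULL) {
  mode <- match.arg(mode)
  kernel <- match.arg(kernel, c("linear", "poly", "rbf"))
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  pos <- isPositive(labels)
  keep <- stats::complete.cases(x)
  if (!all(keep)) {
    message(sum(!keep), " subject(s) dropped for missing features")
    x <- x[keep, , drop = FALSE]
    pos <- pos[keep]
  }
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("need at least 2 subjects per class")
  if (is.null(splits)) splits <- makeSplits(pos, mode, nSplits, trainFrac, seed)
  folds <- lapply(splits, function(sp) evalFold(x, pos, sp, kernel, cost))
  skipped <- vapply(folds, is.null, logical(1))
  if (any(skipped)) warning(sum(skipped), " degenerate fold(s) skipped")
  folds <- do.call(rbind, folds[!skipped])
  if (is.null(folds)) stop("no usable folds")
  new("ClassificationReport",
      featureSet = featureSet, kernel = kernel,
      accuracy = 100 * mean(folds$accuracy),
      sensitivity = 100 * mean(folds$sensitivity),
      specificity = 100 * mean(folds$specificity),
      auc = 100 * mean(folds$auc),
      nFolds = nrow(folds), seed = as.integer(seed),
      foldMetrics = folds, mode = mode)
}

#' Run all three SVM kernels on identical folds and keep the best
#'
#' Linear, polynomial and RBF kernels are evaluated on the same
#' resampling plan; the report maximizing AUC is returned, with ties
#' broken by accuracy and then by kernel simplicity (linear before poly
#' before rbf).
#'
#' @inheritParams crossValidatedSVM
#' @return the winning \code{\linkS4class{ClassificationReport}}.
#' @export
selectBestKernel <- function(features, labels, seed = 1L,
                             mode = c("repeated_split", "kfold"),
                             nSplits = 5L, trainFrac = 0.7, cost = 1,
                             featureSet = "features") {
  mode <- match.arg(mode)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  pos <- isPositive(labels)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  pos <- pos[keep]
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("need at least 2 subjects per class")
  splits <- makeSplits(pos, mode, nSplits, trainFrac, seed)
  reports <- lapply(c("linear", "poly", "rbf"), function(k)
    crossValidatedSVM(x, pos, kernel = k, seed = seed, mode = mode,
                      nSplits = nSplits, trainFrac = trainFrac, cost = cost,
                      featureSet = featureSet, splits = splits))
  auc <- vapply(reports, function(r) r@auc, numeric(1))
  acc <- vapply(reports, function(r) r@accuracy, numeric(1))
  ord <- order(-auc, -acc, seq_along(reports))  # simplicity tie-break last
  reports[[ord[1]]]
}

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf(paste0("ClassificationReport [%s] kernel=%s (%s, %d folds)\n",
                     "  accuracy %.1f%% | sensitivity %.1f%% | ",
                     "specificity %.1f%% | AUC %.1f%%\n"),
              object@featureSet, object@kernel, object@mode, object@nFolds,
              object@accuracy, object@sensitivity, object@specificity,
              object@auc))
})

#' @describeIn crossValidatedSVM extract the report metrics as a one-row
#'   data.frame (percent scale).
#' @param report a \code{ClassificationReport}.
#' @export
reportMetrics <- function(report) {
  stopifnot(is(report, "ClassificationReport"))
  data.frame(feature_set = report@featureSet, kernel = report@kernel,
             accuracy = report@accuracy, sensitivity = report@sensitivity,
             specificity = report@specificity, auc = report@auc,
             n_folds = report@nFolds, mode = report@mode, seed = report@seed,
             stringsAsFactors = FALSE)
}
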