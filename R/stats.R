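#' Choose between t-test and Mann-Whitney U by a normality gate
#'
#' Shapiro-Wilk is applied to each sample at alpha = 0.05; the Student
#' t-test is used only if both samples pass, otherwise the Mann-Whitney
#' U test.  Constant samples (Shapiro-Wilk undefined) are treated as
#' non-normal.
#'
#' @param x,y numeric samples, each with at least 3 finite values.
#' @param alpha normality-gate significance level.
#' @return \code{"t_test"} or \code{"mann_whitney"}.
#' @export
chooseTest <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop("each sample needs at least 3 finite values")
  normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }
  if (normal(x) && normal(y)) "t_test" else "mann_whitney"
}

#' Compare one feature between two groups
#'
#' Two-sided test selected by the normality gate of
#' \code{\link{chooseTest}}; missing values are dropped.  Group means and
#' SDs are reported alongside the raw p-value (FDR adjustment happens at
#' the family level in \code{\link{summarizeCohort}}).  Two identical
#' zero-variance samples yield p = 1 by convention.
#'
#' @param x,y numeric samples (group 1, group 2).
#' @param feature label carried into the result.
#' @return one-row data.frame: feature, mean/SD per group, test_used,
#'   p_raw.
#' @export
compareFeature <- function(x, y, feature = NA_character_) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  test <- chooseTest(x, y)
  p <- if (stats::sd(c(x, y)) == 0) {
    1  # all values identical: no evidence of any effect
  } else if (test == "t_test") {
    stats::t.test(x, y, var.equal = TRUE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
  data.frame(feature = feature,
             mean_group1 = mean(x), sd_group1 = stats::sd(x),
             mean_group2 = mean(y), sd_group2 = stats::sd(y),
             n_group1 = length(x), n_group2 = length(y),
             test_used = test, p_raw = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Group comparison of every feature in a cohort table
#'
#' Runs the gated two-group test on each feature column and applies
#' Benjamini-Hochberg FDR within each feature family: FD features
#' (columns prefixed \code{fd_}) and texture features (prefixed
#' \code{tex_}) are adjusted separately, mirroring analyses that report
#' the two families in separate tables; any other columns form a third
#' family.  Significance is declared at adjusted p < 0.05.
#'
#' @param table data.frame with a group label column and numeric feature
#'   columns (see \code{\link{cohortFeatureTable}}).
#' @param labelCol name of the label column (levels LGG, HGG; group 1 is
#'   LGG).
#' @return data.frame of per-feature results with columns feature, family,
#'   group means/SDs, test_used, p_raw, p_adjusted, significant.
#' @export
summarizeCohort <- function(table, labelCol = "label") {
  stopifnot(is.data.frame(table), labelCol %in% names(table))
  featCols <- names(table)[vapply(table, is.numeric, logical(1))]
  featCols <- setdiff(featCols, labelCol)
  if (length(featCols) == 0L)
    return(data.frame(feature = character(), family = character(),
                      mean_group1 = numeric(), sd_group1 = numeric(),
                      mean_group2 = numeric(), sd_group2 = numeric(),
                      n_group1 = integer(), n_group2 = integer(),
                      test_used = character(), p_raw = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  g1 <- table[[labelCol]] == "LGG"
  rows <- lapply(featCols, function(f) {
    x <- table[[f]][g1]
    y <- table[[f]][!g1]
    r <- if (sum(is.finite(x)) < 3L || sum(is.finite(y)) < 3L) {
      # too few observations (e.g. a feature missing for most subjects)
      data.frame(feature = f,
                 mean_group1 = mean(x, na.rm = TRUE),
                 sd_group1 = stats::sd(x[is.finite(x)]),
                 mean_group2 = mean(y, na.rm = TRUE),
                 sd_group2 = stats::sd(y[is.finite(y)]),
                 n_group1 = sum(is.finite(x)), n_group2 = sum(is.finite(y)),
                 test_used = NA_character_, p_raw = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      compareFeature(x, y, feature = f)
    }
    r$family <- if (startsWith(f, "fd_")) "fd"
      else if (startsWith(f, "tex_")) "texture" else "other"
    r
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$p_adjusted[sel] <- fdrAdjust(out$p_raw[sel])
  }
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < 0.05
  out[, c("feature", "family", "mean_group1", "sd_group1", "mean_group2",
          "sd_group2", "n_group1", "n_group2", "test_used", "p_raw",
          "p_adjusted", "significant")]
}
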